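test_that("typical profiles are per-factor arithmetic means", {
  cohort <- tiny_cohort(10, seed = 41)

  # brute-force mean oracle, computed long-hand per factor
  tp <- typical_profile(cohort, "case")
  sub <- cohort[cohort$group == "case", ]
  for (col in c("FII_pct", "FVIII_pct", "TF_pM", "TFPI_U_per_mL")) {
    long_hand <- sum(sub[[col]]) / nrow(sub)
    expect_equal(tp[[col]], long_hand)
  }

  # a subset of identical donors averages to that donor
  same <- cohort[rep(1, 3), ]
  same$donor_id <- c("a", "b", "c")
  tp2 <- typical_profile(same, same$group[1])
  expect_equal(tp2$FIX_pct, cohort$FIX_pct[1])

  # two donors at 80% and 120% -> 100%
  two <- cohort[1:2, ]
  two$group <- "case"
  two$FII_pct <- c(80, 120)
  expect_equal(typical_profile(two, "case")$FII_pct, 100)

  expect_error(typical_profile(cohort, "case", "other"), "no donors")
})

test_that("identical factors contribute zero; lone differences explain the gap", {
  cohort <- tiny_cohort(10, seed = 43)
  case_t <- typical_profile(cohort, "case")
  ctrl_t <- case_t # start from identical panels
  ctrl_t$TF_pM <- case_t$TF_pM * 0.7 # only TF differs

  oc <- oat_contributions(case_t, ctrl_t, the_scheme, horizon = 900)
  tf_row <- oc[oc$factor == "TF", ]
  others <- oc[oc$factor != "TF", ]
  expect_true(all(abs(others$d_peak_M) <= 1e-9 * abs(tf_row$d_peak_M) +
                    1e-16))

  # TF substitution reproduces the whole case-control gap
  full_gap <- summarize_trajectory(
    simulate_donor(panel_to_profile(ctrl_t, the_scheme), the_scheme,
                   horizon = 900), the_scheme)$peak_FIIa_M -
    summarize_trajectory(
      simulate_donor(panel_to_profile(case_t, the_scheme), the_scheme,
                     horizon = 900), the_scheme)$peak_FIIa_M
  expect_equal(tf_row$d_peak_M, full_gap, tolerance = 1e-6)
})

test_that("contributions do not depend on assessment order", {
  cohort <- tiny_cohort(10, seed = 47)
  case_t <- typical_profile(cohort, "case")
  ctrl_t <- typical_profile(cohort, "control")
  fwd <- oat_contributions(case_t, ctrl_t, the_scheme, horizon = 900,
                           factors = c("TF", "FVIII", "FIX"))
  rev_ <- oat_contributions(case_t, ctrl_t, the_scheme, horizon = 900,
                            factors = c("FIX", "FVIII", "TF"))
  for (f in c("TF", "FVIII", "FIX")) {
    expect_equal(fwd$d_peak_M[fwd$factor == f],
                 rev_$d_peak_M[rev_$factor == f])
  }
})

test_that("sequential adjustment converges on the typical control", {
  cohort <- tiny_cohort(12, seed = 53)
  case_t <- typical_profile(cohort, "case")
  ctrl_t <- typical_profile(cohort, "control")

  # empty order: single unadjusted entry
  s0 <- sequential_adjustment(case_t, ctrl_t, character(0), the_scheme,
                              horizon = 900)
  expect_equal(nrow(s0), 1)
  base <- summarize_trajectory(
    simulate_donor(panel_to_profile(case_t, the_scheme), the_scheme,
                   horizon = 900), the_scheme)
  expect_equal(s0$peak_FIIa_M, base$peak_FIIa_M)

  # all nine factors: full-substitution identity to < 0.5%
  all9 <- c("FII", "FV", "FVII", "FVIII", "FIX", "FX", "AT", "TF", "TFPI")
  seq9 <- sequential_adjustment(case_t, ctrl_t, all9, the_scheme,
                                horizon = 900)
  expect_equal(nrow(seq9), 10)
  ctrl <- summarize_trajectory(
    simulate_donor(panel_to_profile(ctrl_t, the_scheme), the_scheme,
                   horizon = 900), the_scheme)
  rel <- abs(seq9$peak_FIIa_M[10] - ctrl$peak_FIIa_M) / ctrl$peak_FIIa_M
  expect_lt(rel, 0.005)

  expect_error(
    sequential_adjustment(case_t, ctrl_t, c("TF", "TF"), the_scheme),
    "duplicate")
  expect_error(
    sequential_adjustment(case_t, ctrl_t, "FXIII", the_scheme),
    "unknown")
})

test_that("reported driver orders run and shrink the peak gap", {
  # cohorts synthesised with the study's effect directions
  cohort <- generate_cohort(synthetic_cohort_config(n_cases = 40,
                                                    n_controls = 40),
                            seed = 59)
  orders <- list(male = c("FVIII", "TF", "TFPI", "FIX"),
                 female = c("FII", "FIX", "FVIII"))
  for (ord in orders) {
    case_t <- typical_profile(cohort, "case")
    ctrl_t <- typical_profile(cohort, "control")
    steps <- sequential_adjustment(case_t, ctrl_t, ord, the_scheme,
                                   horizon = 900)
    ctrl_peak <- summarize_trajectory(
      simulate_donor(panel_to_profile(ctrl_t, the_scheme), the_scheme,
                     horizon = 900), the_scheme)$peak_FIIa_M
    gaps <- abs(steps$peak_FIIa_M - ctrl_peak)
    expect_lt(gaps[length(gaps)], gaps[1])
  }
})

test_that("automatic ordering ranks by absolute peak contribution", {
  contribs <- data.frame(
    factor = c("A", "B", "C", "D"),
    d_peak_M = c(-2e-9, 5e-9, 2e-9, -5e-9),
    d_time_to_peak_s = c(1, 2, 3, 1),
    error = NA_character_, stringsAsFactors = FALSE)
  expect_equal(driver_order(contribs), c("B", "D", "C", "A"))
})
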