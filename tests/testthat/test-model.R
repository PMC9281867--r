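test_that("prothrombin derivative matches the mass-action balance", {
  s <- the_scheme
  state <- setNames(numeric(34), s$species)

  # only FII present: every FII term contains FXa or a prothrombinase species
  state["FII"] <- 1.4e-6
  d <- derivative(state, s)
  expect_equal(unname(d["FII"]), 0)
  expect_true(all(d == 0))

  # direct substitution: dFII/dt = -k16 [Xa][II] when complexes are absent
  state["FXa"] <- 1e-9
  d <- derivative(state, s)
  expect_equal(unname(d["FII"]), -7.5e3 * 1e-9 * 1.4e-6)

  # full three-term balance with prothrombinase species populated
  state["Xa:Va"] <- 2e-10
  state["Xa:Va:II"] <- 5e-11
  d <- derivative(state, s)
  expected <- -7.5e3 * state[["FXa"]] * state[["FII"]] -
    1e8 * state[["Xa:Va"]] * state[["FII"]] +
    103 * state[["Xa:Va:II"]]
  expect_equal(unname(d["FII"]), unname(expected))
})

test_that("derivative agrees with finite differences of a simulation", {
  s <- the_scheme
  traj <- simulate_donor(donor_profile(), s, horizon = 900, grid = 0.05)
  set.seed(3)
  idx <- sample(seq(200, length(traj$time) - 200), 20)
  h <- 0.05
  for (i in idx) {
    state <- traj$conc[i, ]
    d <- derivative(state, s)
    fd <- (traj$conc[i + 1, ] - traj$conc[i - 1, ]) / (2 * h)
    scale <- max(abs(fd))
    expect_lt(max(abs(d - fd)) / scale, 1e-3)
  }
})

test_that("compiled and R engines produce the same trajectory", {
  p <- donor_profile()
  tc <- simulate_donor(p, the_scheme, horizon = 400)
  tr <- simulate_donor(p, the_scheme, horizon = 400, engine = "R")
  expect_lt(max(abs(tc$conc - tr$conc)) / max(tc$conc), 1e-7)
})

test_that("without an activation source the cascade is silent", {
  p <- donor_profile(TF = 0, FVIIa = 0)
  traj <- simulate_donor(p, the_scheme)
  activated <- c("FIIa", "mIIa", "FXa", "FIXa", "FVa", "FVIIIa",
                 "TF:VIIa", "Xa:Va", "IXa:VIIIa")
  expect_true(all(traj$conc[, activated] == 0))

  # free FVIIa alone cannot initiate: it appears in no catalytic reaction
  p2 <- donor_profile(TF = 0)
  traj2 <- simulate_donor(p2, the_scheme)
  expect_equal(max(traj2$conc[, "FIIa"]), 0)
})

test_that("all lineages are conserved along seeded random simulations", {
  set.seed(101)
  for (i in 1:10) {
    traj <- simulate_donor(random_profile(), the_scheme, horizon = 600)
    drift <- check_conservation(traj, the_scheme)
    expect_lt(max(drift), 1e-6)
  }
})

test_that("lineage totals equal their initial factor concentrations", {
  p <- donor_profile()
  traj <- simulate_donor(p, the_scheme)
  totals <- conserved_totals(traj, the_scheme)
  expect_equal(unname(totals[1, "II"]), unname(p["FII"]))
  expect_equal(unname(totals[1, "AT"]), unname(p["AT"]))
  expect_equal(unname(totals[1, "VII"]), unname(p["FVII"] + p["FVIIa"]))
  # constancy over time
  expect_lt(max(abs(totals[, "II"] - totals[1, "II"])) / totals[1, "II"],
            1e-6)
  expect_error(conserved_totals(traj, the_scheme, "XIII"), "lineage")
})

test_that("no species goes negative beyond the clipping tolerance", {
  set.seed(17)
  for (i in 1:5) {
    traj <- simulate_donor(random_profile(), the_scheme, horizon = 600)
    expect_true(all(traj$conc >= 0)) # post-clip
  }
})

test_that("peak thrombin responds monotonically to FII and TF", {
  base <- donor_profile()
  peaks <- vapply(c(0.5, 1, 1.5, 2), function(a) {
    p <- base
    p["FII"] <- p["FII"] * a
    max(simulate_donor(p, the_scheme)$conc[, "FIIa"])
  }, 0)
  expect_false(is.unsorted(peaks))

  ttp <- vapply(c(0.5, 1, 1.5, 2), function(a) {
    p <- base
    p["TF"] <- p["TF"] * a
    s <- summarize_trajectory(simulate_donor(p, the_scheme), the_scheme)
    s$time_to_peak_FIIa_s
  }, 0)
  expect_false(is.unsorted(rev(ttp)))
})

test_that("removing the inhibitors never decreases thrombin", {
  set.seed(23)
  for (i in 1:3) {
    p <- random_profile()
    p_free <- p
    p_free["TFPI"] <- 0
    p_free["AT"] <- 0
    s_with <- summarize_trajectory(simulate_donor(p, the_scheme), the_scheme)
    s_free <- summarize_trajectory(simulate_donor(p_free, the_scheme),
                                   the_scheme)
    expect_gte(s_free$peak_FIIa_M, s_with$peak_FIIa_M)
    expect_gte(s_free$thrombin_AUC_Ms, s_with$thrombin_AUC_Ms)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_donor(donor_profile(), the_scheme, horizon = -1),
               "horizon")
  p <- donor_profile()
  p["FII"] <- NaN
  expect_error(simulate_donor(p, the_scheme), "non-finite")
  expect_error(donor_profile(FII = -1), "negative")
})
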