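test_that("normal range is mean plus/minus two sample SDs", {
  r <- normal_range(c(90, 100, 110))
  expect_equal(unname(r["low"]), 80)
  expect_equal(unname(r["high"]), 120)
  expect_equal(attr(r, "mean"), 100)
  expect_equal(attr(r, "sd"), 10)

  # zero-width for constant values
  r0 <- normal_range(rep(42, 5))
  expect_equal(unname(r0["low"]), 42)
  expect_equal(unname(r0["high"]), 42)

  # long-hand oracle on a 50-value fixture
  set.seed(61)
  v <- rnorm(50, 100, 15)
  m <- sum(v) / 50
  s <- sqrt(sum((v - m)^2) / 49)
  r50 <- normal_range(v)
  expect_equal(unname(r50["low"]), m - 2 * s)
  expect_equal(unname(r50["high"]), m + 2 * s)

  expect_error(normal_range(5), "at least two")
})

test_that("unpaired t-test matches base R and a permutation oracle", {
  # identical groups
  g <- c(1, 2, 3, 4)
  res <- compare_groups(g, g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # agreement with stats::t.test on raw samples
  set.seed(67)
  a <- rnorm(12, 10, 2)
  b <- rnorm(15, 11, 2)
  res <- compare_groups(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  # summary-statistic mode reproduces the raw-sample pooled test
  res2 <- compare_groups(n1 = length(a), m1 = mean(a), s1 = sd(a),
                         n2 = length(b), m2 = mean(b), s2 = sd(b))
  expect_equal(res2$t, res$t)
  expect_equal(res2$p, res$p)

  # permutation oracle on an 8-vs-8 fixture
  set.seed(71)
  x <- rnorm(8, 0, 1)
  y <- rnorm(8, 1.2, 1)
  obs <- abs(compare_groups(x, y)$t)
  pool <- c(x, y)
  nperm <- 4000
  hits <- 0
  for (i in seq_len(nperm)) {
    idx <- sample(16, 8)
    hits <- hits + (abs(compare_groups(pool[idx], pool[-idx])$t) >= obs)
  }
  p_perm <- hits / nperm
  p_t <- compare_groups(x, y)$p
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / nperm) + 0.02
  expect_lt(abs(p_perm - p_t), mc_err + 0.03)
})

test_that("degenerate zero-variance groups follow the conventions", {
  res <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$p, 1)
  res2 <- compare_groups(c(5, 5, 5), c(6, 6, 6))
  expect_equal(res2$p, 0)
  expect_error(compare_groups(1, c(1, 2)), "at least two")
})

test_that("chi-squared test matches closed forms and Fisher ordering", {
  # perfectly proportional table
  res <- compare_categorical(matrix(c(20, 10, 40, 20), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # diagonal table: statistic = n = 20 without correction
  res2 <- compare_categorical(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res2$statistic, 20)

  # ordering agrees with Fisher's exact test across small tables
  tables <- list(matrix(c(8, 2, 2, 8), 2), matrix(c(6, 4, 4, 6), 2),
                 matrix(c(5, 5, 5, 5), 2), matrix(c(9, 1, 1, 9), 2))
  p_chi <- vapply(tables, function(tb) compare_categorical(tb)$p, 0)
  p_fis <- vapply(tables, function(tb) fisher.test(tb)$p.value, 0)
  expect_equal(order(p_chi), order(p_fis))

  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_error(compare_categorical(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("carriage frequency reproduces printed percentages", {
  # agreement at the precision the percentages are reported to (2 d.p.)
  expect_equal(carriage_frequency(3, 162), 1.85, tolerance = 0.005)
  expect_equal(carriage_frequency(6, 186), 3.22, tolerance = 0.005)
  expect_equal(carriage_frequency(0, 100), 0)
  expect_error(carriage_frequency(5, 0), "positive")
  expect_error(carriage_frequency(7, 5), "between")
})

test_that("tertile assignment is balanced and matches sort-and-cut", {
  # 9 distinct values -> 3/3/3
  t9 <- tertile_stratify(1:9, letters[1:9])
  expect_equal(as.vector(table(t9)), c(3, 3, 3))

  # 10 donors -> {4,3,3} with the remainder in the lower tertile
  t10 <- tertile_stratify(1:10, letters[1:10])
  expect_equal(as.vector(table(t10)), c(4, 3, 3))
  expect_equal(as.character(t10[["a"]]), "low")
  expect_equal(as.character(t10[["j"]]), "high")

  # brute-force sort-and-cut oracle on 100 random keys
  set.seed(73)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    v <- round(runif(n, 0, 10), 1) # ties likely
    ids <- sprintf("d%03d", seq_len(n))
    got <- tertile_stratify(v, ids)
    ord <- order(v, ids)
    sizes <- n %/% 3 + c((n %% 3) >= 1, (n %% 3) >= 2, 0)
    want <- character(n)
    want[ord] <- rep(c("low", "medium", "high"), times = sizes)
    expect_equal(as.character(got), want)
    expect_lte(diff(range(table(got))), 1)
  }

  # degenerate all-equal keys flagged
  td <- tertile_stratify(rep(1, 6), letters[1:6])
  expect_true(attr(td, "degenerate"))
  expect_error(tertile_stratify(c(1, 2)), "at least three")
})

test_that("pearson correlations match the textbook formula", {
  set.seed(79)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- 0.5 * x + rnorm(20)
    n <- 20
    r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
    expect_equal(unname(cor.test(x, y)$estimate), r_hand,
                 tolerance = 1e-12)
  }
})

test_that("factor-effect correlations detect exact linear relations", {
  cohort <- tiny_cohort(6, seed = 83)
  fake <- data.frame(
    donor_id = rep(cohort$donor_id, 1),
    drug = "testdrug",
    pct_peak_reduction = -2 * cohort$FVIII_pct,
    pct_time_to_peak_change = rep(1, nrow(cohort)),
    stringsAsFactors = FALSE)
  rep_ <- correlate_factors_with_effects(cohort, fake, "peak")
  fviii <- rep_[rep_$factor == "FVIII", ]
  expect_equal(fviii$r, -1, tolerance = 1e-12)
  expect_false(fviii$undefined)

  # constant effect column -> undefined, flagged
  rep2 <- correlate_factors_with_effects(cohort, fake, "time_to_peak")
  expect_true(all(rep2$undefined))
  expect_true(all(is.na(rep2$r)))
})

test_that("heatmap matrix is deterministic and round-trips through CSV", {
  cohort <- tiny_cohort(6, seed = 89)
  summaries <- cohort_summaries(cohort, the_scheme, horizon = 900)
  effects <- data.frame(
    donor_id = rep(cohort$donor_id, 2),
    drug = rep(c("a_drug", "b_drug"), each = nrow(cohort)),
    pct_peak_reduction = runif(2 * nrow(cohort), 0, 100),
    pct_time_to_peak_change = runif(2 * nrow(cohort), 0, 50),
    stringsAsFactors = FALSE)

  hm1 <- heatmap_matrix(cohort, summaries, drug_effects = effects)
  hm2 <- heatmap_matrix(cohort, summaries, drug_effects = effects)
  expect_identical(hm1, hm2)
  expect_equal(nrow(hm1), 6)
  expect_true(all(c("TF_tertile", "FVIII_tertile", "sex", "group",
                    "a_drug_pct_peak_reduction") %in% names(hm1)))
  # rows grouped by tertile, high first
  expect_false(is.unsorted(match(hm1$thrombin_tertile,
                                 c("high", "medium", "low"))))

  tmp <- tempfile(fileext = ".csv")
  write.csv(hm1, tmp, row.names = FALSE)
  back <- read.csv(tmp, stringsAsFactors = FALSE)
  expect_equal(back$donor_id, hm1$donor_id)
  expect_equal(back$key_value, hm1$key_value, tolerance = 1e-12)

  expect_warning(heatmap_matrix(cohort, summaries), "drug columns omitted")
})
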