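#' Default synthetic-cohort configuration
#'
#' Emulates the structure of the study cohort the pipeline was designed for:
#' 162 cases and 186 controls, ~86%/87% male, cases with elevated TF, FVIII,
#' FIX and FX and reduced TFPI, females with elevated FVIII (and, among
#' cases, FII and FIX), a prothrombin-20210A minor-allele frequency below 4%
#' whose carriers have elevated FII, and per-factor dispersions sized so that
#' a mean plus/minus two SD normal range is meaningful. Multipliers are
#' modest synthetic effect directions, not estimates of any cohort's effect
#' sizes. TF and FVIII are drawn lognormal (right-skewed); the other factors
#' are normal truncated at zero.
#'
#' @param n_cases,n_controls Group sizes.
#' @param male_fraction Named numeric, `case` and `control` male fractions.
#' @param baseline Named list per factor: `mean` and `sd` in assay units for
#'   male controls.
#' @param case_multiplier,female_multiplier,female_case_multiplier Named
#'   numeric multipliers (> 0) applied to the baseline mean for cases, for
#'   females of both groups, and additionally for female cases.
#' @param family Named character: `"lognormal"` or `"truncnorm"` per factor.
#' @param maf_20210 Minor-allele frequency of prothrombin 20210A.
#' @param fii_multiplier_20210 FII mean multiplier for GA carriers.
#' @return List of class `synth_config`.
#' @export
synthetic_cohort_config <- function(
    n_cases = 162, n_controls = 186,
    male_fraction = c(case = 0.86, control = 0.87),
    baseline = list(
      FII_pct = list(mean = 100, sd = 15),
      FV_pct = list(mean = 100, sd = 18),
      FVII_pct = list(mean = 100, sd = 20),
      FVIII_pct = list(mean = 100, sd = 25),
      FIX_pct = list(mean = 100, sd = 18),
      FX_pct = list(mean = 100, sd = 15),
      AT_pct = list(mean = 100, sd = 10),
      TF_pM = list(mean = 5, sd = 2),
      TFPI_U_per_mL = list(mean = 1, sd = 0.25)),
    case_multiplier = c(TF_pM = 1.25, FVIII_pct = 1.2, FIX_pct = 1.15,
                        FX_pct = 1.1, TFPI_U_per_mL = 0.9),
    female_multiplier = c(FVIII_pct = 1.15),
    female_case_multiplier = c(FII_pct = 1.1, FIX_pct = 1.15),
    family = c(TF_pM = "lognormal", FVIII_pct = "lognormal"),
    maf_20210 = 0.02,
    fii_multiplier_20210 = 1.25) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              male_fraction = male_fraction, baseline = baseline,
              case_multiplier = case_multiplier,
              female_multiplier = female_multiplier,
              female_case_multiplier = female_case_multiplier,
              family = family, maf_20210 = maf_20210,
              fii_multiplier_20210 = fii_multiplier_20210)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_cases <= 0 || cfg$n_controls <= 0) {
    stop("group sizes must be positive")
  }
  if (any(cfg$male_fraction < 0) || any(cfg$male_fraction > 1)) {
    stop("male fractions must be in [0, 1]")
  }
  for (f in names(cfg$baseline)) {
    b <- cfg$baseline[[f]]
    if (b$mean <= 0) stop("baseline mean for ", f, " must be positive")
    if (b$sd < 0) stop("baseline sd for ", f, " must be nonnegative")
  }
  mults <- c(cfg$case_multiplier, cfg$female_multiplier,
             cfg$female_case_multiplier, cfg$fii_multiplier_20210)
  if (any(mults <= 0)) stop("multipliers must be positive")
  if (cfg$maf_20210 < 0 || cfg$maf_20210 > 1) {
    stop("minor-allele frequency must be in [0, 1]")
  }
  invisible(cfg)
}

# draw length(mean) values with the configured means/sds and family
draw_levels <- function(mean, sd, family) {
  n <- length(mean)
  if (all(sd == 0)) {
    return(mean)
  }
  if (identical(family, "lognormal")) {
    # moment-match the target arithmetic mean and sd
    sigma2 <- log(1 + (sd / mean)^2)
    mu <- log(mean) - sigma2 / 2
    return(stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2)))
  }
  v <- stats::rnorm(n, mean, sd)
  while (any(v <= 0)) { # truncate at zero by redrawing
    bad <- v <= 0
    v[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  v
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-donor factor panels under the configuration's group sizes, sex
#' ratios, effect-direction multipliers, distribution families and genotype
#' model. Sex counts are deterministic (`round(fraction * n)` males per
#' group); all randomness flows from `seed`, so the same seed reproduces the
#' cohort bit-identically.
#'
#' @param config A `synth_config` (default [synthetic_cohort_config()]).
#' @param seed Integer RNG seed.
#' @return Cohort data frame in the standard column layout.
#' @export
generate_cohort <- function(config = synthetic_cohort_config(), seed = 1) {
  validate_synth_config(config)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)

  make_group <- function(group, n, prefix) {
    n_male <- round(config$male_fraction[[group]] * n)
    sex <- rep(c("male", "female"), c(n_male, n - n_male))
    # genotype: GA with probability 2 maf (1 - maf), AA with maf^2
    maf <- config$maf_20210
    u <- stats::runif(n)
    genotype <- ifelse(u < maf^2, "AA",
                       ifelse(u < maf^2 + 2 * maf * (1 - maf), "GA", "GG"))
    panel <- data.frame(donor_id = sprintf("%s%04d", prefix, seq_len(n)),
                        group = group, sex = sex,
                        genotype_20210 = genotype,
                        stringsAsFactors = FALSE)
    for (f in names(config$baseline)) {
      b <- config$baseline[[f]]
      m <- b$mean
      if (group == "case" && f %in% names(config$case_multiplier)) {
        m <- m * config$case_multiplier[[f]]
      }
      mvec <- rep(m, n)
      if (f %in% names(config$female_multiplier)) {
        mvec[sex == "female"] <- mvec[sex == "female"] *
          config$female_multiplier[[f]]
      }
      if (group == "case" && f %in% names(config$female_case_multiplier)) {
        mvec[sex == "female"] <- mvec[sex == "female"] *
          config$female_case_multiplier[[f]]
      }
      if (f == "FII_pct") {
        carrier <- genotype %in% c("GA", "AA")
        mvec[carrier] <- mvec[carrier] * config$fii_multiplier_20210
      }
      sdvec <- b$sd * mvec / b$mean # constant coefficient of variation
      fam <- if (f %in% names(config$family)) config$family[[f]] else
        "truncnorm"
      panel[[f]] <- draw_levels(mvec, sdvec, fam)
    }
    panel
  }

  cases <- make_group("case", config$n_cases, "C")
  controls <- make_group("control", config$n_controls, "H")
  cohort <- rbind(cases, controls)
  validate_cohort(cohort)
  cohort
}
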