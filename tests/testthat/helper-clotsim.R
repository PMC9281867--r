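# Shared fixtures: load the packaged scheme once; generators for random
# donor profiles and small in-memory cohorts.

the_scheme <- build_default_scheme()

# random physiological-range profile: each factor scaled 0.5-2x its
# reference value, TF between 1 and 20 pM
random_profile <- function() {
  donor_profile(
    TF = runif(1, 1, 20) * 1e-12,
    FII = 1.4e-6 * runif(1, 0.5, 2),
    FV = 2e-8 * runif(1, 0.5, 2),
    FVII = 9.9e-9 * runif(1, 0.5, 2),
    FVIIa = 1e-10 * runif(1, 0.5, 2),
    FVIII = 7e-10 * runif(1, 0.5, 2),
    FIX = 9e-8 * runif(1, 0.5, 2),
    FX = 1.6e-7 * runif(1, 0.5, 2),
    TFPI = 2.5e-9 * runif(1, 0.5, 2),
    AT = 3.4e-6 * runif(1, 0.5, 2))
}

# random assay-unit panel
random_panel <- function(id = "d1", group = "control", sex = "male") {
  factor_panel(donor_id = id, group = group, sex = sex,
               FII_pct = runif(1, 50, 200), FV_pct = runif(1, 50, 200),
               FVII_pct = runif(1, 50, 200), FVIII_pct = runif(1, 50, 200),
               FIX_pct = runif(1, 50, 200), FX_pct = runif(1, 50, 200),
               AT_pct = runif(1, 50, 200), TF_pM = runif(1, 1, 20),
               TFPI_U_per_mL = runif(1, 0.5, 2))
}

# small deterministic cohort for pipeline tests
tiny_cohort <- function(n = 6, seed = 11) {
  cfg <- synthetic_cohort_config(n_cases = ceiling(n / 2),
                                 n_controls = floor(n / 2))
  generate_cohort(cfg, seed = seed)
}
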