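# factor labels used in driver analysis (assay-unit columns)
driver_factors <- function() {
  c(FII = "FII_pct", FV = "FV_pct", FVII = "FVII_pct", FVIII = "FVIII_pct",
    FIX = "FIX_pct", FX = "FX_pct", AT = "AT_pct", TF = "TF_pM",
    TFPI = "TFPI_U_per_mL")
}

#' Typical-donor profile of a cohort subset
#'
#' Arithmetic per-factor mean, in assay units, over a cohort subset selected
#' by group and optionally sex — the "typical case donor" / "typical control
#' donor" construction used for key-driver analysis.
#'
#' @param cohort Cohort data frame.
#' @param group `"case"` or `"control"`.
#' @param sex Optional `"male"` or `"female"` to stratify by sex.
#' @return A `factor_panel` whose levels are the subset means and whose
#'   `donor_id` records the subset (e.g. `"typical_case_male"`).
#' @export
typical_profile <- function(cohort, group, sex = NULL) {
  validate_cohort(cohort)
  keep <- cohort$group == group
  if (!is.null(sex)) {
    keep <- keep & cohort$sex == sex
  }
  subset <- cohort[keep, , drop = FALSE]
  if (nrow(subset) == 0) {
    stop("no donors in subset group='", group, "'",
         if (!is.null(sex)) paste0(", sex='", sex, "'") else "")
  }
  means <- vapply(panel_factor_columns(), function(col) mean(subset[[col]]),
                  0)
  factor_panel(
    donor_id = paste0("typical_", group,
                      if (!is.null(sex)) paste0("_", sex) else ""),
    group = group,
    sex = if (is.null(sex)) "male" else sex,
    genotype_20210 = "unknown",
    FII_pct = means[["FII_pct"]], FV_pct = means[["FV_pct"]],
    FVII_pct = means[["FVII_pct"]], FVIII_pct = means[["FVIII_pct"]],
    FIX_pct = means[["FIX_pct"]], FX_pct = means[["FX_pct"]],
    AT_pct = means[["AT_pct"]], TF_pM = means[["TF_pM"]],
    TFPI_U_per_mL = means[["TFPI_U_per_mL"]])
}

# replace the named factors in panel `a` with their values in panel `b`
substitute_factors <- function(a, b, factors) {
  cols <- driver_factors()
  unknown <- setdiff(factors, names(cols))
  if (length(unknown) > 0) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  }
  for (f in factors) {
    a[[cols[[f]]]] <- b[[cols[[f]]]]
  }
  a
}

#' One-at-a-time factor contributions to a case-control gap
#'
#' For each measured factor, simulates the typical-case profile with that
#' single factor replaced by its typical-control level and reports the
#' resulting change in peak thrombin and time to peak. Because the cascade is
#' nonlinear the contributions need not sum to the total gap.
#'
#' @param case_typical,control_typical `factor_panel`s (see
#'   [typical_profile()]).
#' @param scheme A `coag_scheme`.
#' @param factors Factors to assess (default: all nine measured quantities).
#' @param ... Passed to [simulate_donor()].
#' @return Data frame ordered as `factors`: `factor`, `d_peak_M`,
#'   `d_peak_pct`, `d_time_to_peak_s`, `d_time_to_peak_pct`, `error`.
#'   Deltas are (substituted - case), so a negative `d_peak_M` means moving
#'   that factor to its control level lowers peak thrombin.
#' @export
oat_contributions <- function(case_typical, control_typical, scheme,
                              factors = names(driver_factors()), ...) {
  base <- summarize_trajectory(
    simulate_donor(panel_to_profile(case_typical, scheme), scheme, ...),
    scheme)
  rows <- lapply(factors, function(f) {
    tryCatch({
      sub <- substitute_factors(case_typical, control_typical, f)
      s <- summarize_trajectory(
        simulate_donor(panel_to_profile(sub, scheme), scheme, ...), scheme)
      data.frame(
        factor = f,
        d_peak_M = s$peak_FIIa_M - base$peak_FIIa_M,
        d_peak_pct = 100 * (s$peak_FIIa_M - base$peak_FIIa_M) /
          base$peak_FIIa_M,
        d_time_to_peak_s = s$time_to_peak_FIIa_s - base$time_to_peak_FIIa_s,
        d_time_to_peak_pct = 100 *
          (s$time_to_peak_FIIa_s - base$time_to_peak_FIIa_s) /
          base$time_to_peak_FIIa_s,
        error = NA_character_,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(factor = f, d_peak_M = NA_real_, d_peak_pct = NA_real_,
                 d_time_to_peak_s = NA_real_, d_time_to_peak_pct = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank factors for sequential adjustment
#'
#' Orders factors by descending absolute peak-thrombin contribution, ties
#' broken by absolute time-to-peak contribution, then factor name.
#'
#' @param contributions Output of [oat_contributions()].
#' @return Character vector of factor names, most influential first.
#' @export
driver_order <- function(contributions) {
  ok <- contributions[is.na(contributions$error), , drop = FALSE]
  ord <- order(-abs(ok$d_peak_M), -abs(ok$d_time_to_peak_s), ok$factor)
  ok$factor[ord]
}

#' Sequential adjustment of a typical case toward a typical control
#'
#' Step k replaces the first k factors of `order` in the typical-case panel
#' with their typical-control levels (cumulatively) and re-simulates. With
#' all nine factors adjusted the summary reproduces the typical-control
#' simulation.
#'
#' @param case_typical,control_typical `factor_panel`s.
#' @param order Character vector of factors to adjust, in order; no
#'   duplicates. May be empty, giving only the unadjusted case entry.
#' @param scheme A `coag_scheme`.
#' @param ... Passed to [simulate_donor()].
#' @return Data frame with one row per step (step 0 = unadjusted case):
#'   `step`, `adjusted` (comma-separated factors so far), and the summary
#'   columns of [summarize_trajectory()].
#' @export
sequential_adjustment <- function(case_typical, control_typical, order,
                                  scheme, ...) {
  if (anyDuplicated(order)) {
    stop("duplicate factor in adjustment order")
  }
  unknown <- setdiff(order, names(driver_factors()))
  if (length(unknown) > 0) {
    stop("unknown factor(s) in order: ", paste(unknown, collapse = ", "))
  }
  steps <- vector("list", length(order) + 1)
  for (k in 0:length(order)) {
    panel <- substitute_factors(case_typical, control_typical,
                                order[seq_len(k)])
    s <- summarize_trajectory(
      simulate_donor(panel_to_profile(panel, scheme), scheme, ...), scheme)
    steps[[k + 1]] <- cbind(
      data.frame(step = k,
                 adjusted = paste(order[seq_len(k)], collapse = ","),
                 stringsAsFactors = FALSE),
      s)
  }
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  out
}
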