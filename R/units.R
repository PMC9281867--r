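#' Create a factor panel
#'
#' A factor panel is one donor's measured plasma levels in assay units:
#' clotting-factor activities FII, FV, FVII, FVIII, FIX, FX and antithrombin
#' as percent of a reference plasma, tissue factor activity in pM, and TFPI
#' activity in U/mL, plus donor metadata.
#'
#' @param donor_id Donor identifier.
#' @param group `"case"` or `"control"`.
#' @param sex `"male"` or `"female"`.
#' @param genotype_20210 Prothrombin G20210A genotype: `"GG"`, `"GA"`,
#'   `"AA"` or `"unknown"`.
#' @param FII_pct,FV_pct,FVII_pct,FVIII_pct,FIX_pct,FX_pct,AT_pct Percent of
#'   reference plasma.
#' @param TF_pM Tissue factor activity, pM.
#' @param TFPI_U_per_mL TFPI activity, U/mL.
#' @return One-row data frame of class `factor_panel`.
#' @export
factor_panel <- function(donor_id, group = c("control", "case"),
                         sex = c("male", "female"),
                         genotype_20210 = "GG",
                         FII_pct = 100, FV_pct = 100, FVII_pct = 100,
                         FVIII_pct = 100, FIX_pct = 100, FX_pct = 100,
                         AT_pct = 100, TF_pM = 5, TFPI_U_per_mL = 1) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  if (!genotype_20210 %in% c("GG", "GA", "AA", "unknown")) {
    stop("genotype_20210 must be GG, GA, AA or unknown")
  }
  panel <- data.frame(donor_id = as.character(donor_id), group = group,
                      sex = sex, genotype_20210 = genotype_20210,
                      FII_pct = FII_pct, FV_pct = FV_pct,
                      FVII_pct = FVII_pct, FVIII_pct = FVIII_pct,
                      FIX_pct = FIX_pct, FX_pct = FX_pct, AT_pct = AT_pct,
                      TF_pM = TF_pM, TFPI_U_per_mL = TFPI_U_per_mL,
                      stringsAsFactors = FALSE)
  validate_panel(panel)
  class(panel) <- c("factor_panel", "data.frame")
  panel
}

# the nine measured quantities, in cohort-CSV column order
panel_factor_columns <- function() {
  c("FII_pct", "FV_pct", "FVII_pct", "FVIII_pct", "FIX_pct", "FX_pct",
    "AT_pct", "TF_pM", "TFPI_U_per_mL")
}

validate_panel <- function(panel) {
  for (col in panel_factor_columns()) {
    if (is.null(panel[[col]])) {
      stop("panel is missing measured factor '", col, "'")
    }
    v <- panel[[col]]
    if (any(!is.finite(v))) {
      stop("panel factor '", col, "' contains non-finite values")
    }
    if (any(v < 0)) {
      stop("panel factor '", col, "' contains negative levels")
    }
  }
  pct_cols <- panel_factor_columns()[1:7]
  if (any(as.matrix(panel[pct_cols]) >= 500)) {
    warning("percent-of-reference level >= 500% looks implausible")
  }
  invisible(panel)
}

#' Convert an assay-unit factor panel to molar initial conditions
#'
#' Percent-of-reference factors are scaled linearly against the reference
#' plasma concentration table (level/100 x reference molar concentration); TF
#' activity in pM is taken directly as the model TF concentration; TFPI in
#' U/mL is scaled by the molar concentration equivalent to 1 U/mL. Total FVII
#' is split into zymogen FVII and trace FVIIa using the scheme's
#' `fviia_fraction` (default 1%), without which the cascade cannot initiate.
#'
#' @param panel A `factor_panel` (or one row of a cohort table).
#' @param scheme A `coag_scheme` providing the reference table.
#' @param fviia_fraction Fraction of total FVII circulating as FVIIa;
#'   defaults to the scheme's `initial$fviia_fraction`.
#' @return A `donor_profile` of molar initial conditions.
#' @export
panel_to_profile <- function(panel, scheme, fviia_fraction = NULL) {
  validate_panel(panel)
  if (is.null(fviia_fraction)) {
    fviia_fraction <- scheme$initial$fviia_fraction
  }
  ref <- scheme$reference
  vii_total <- panel$FVII_pct / 100 * ref[["FVII"]]
  donor_profile(
    TF = panel$TF_pM * 1e-12,
    FII = panel$FII_pct / 100 * ref[["FII"]],
    FV = panel$FV_pct / 100 * ref[["FV"]],
    FVII = (1 - fviia_fraction) * vii_total,
    FVIIa = fviia_fraction * vii_total,
    FVIII = panel$FVIII_pct / 100 * ref[["FVIII"]],
    FIX = panel$FIX_pct / 100 * ref[["FIX"]],
    FX = panel$FX_pct / 100 * ref[["FX"]],
    TFPI = panel$TFPI_U_per_mL * ref[["TFPI"]],
    AT = panel$AT_pct / 100 * ref[["AT"]])
}

#' Convert a molar profile back to assay units
#'
#' Exact inverse of [panel_to_profile()] on the measured-factor subspace
#' (total FVII = FVII + FVIIa).
#'
#' @param profile A `donor_profile`.
#' @param scheme A `coag_scheme`.
#' @param donor_id,group,sex,genotype_20210 Metadata for the emitted panel.
#' @return A `factor_panel`.
#' @export
profile_to_panel <- function(profile, scheme, donor_id = "donor",
                             group = "control", sex = "male",
                             genotype_20210 = "unknown") {
  ref <- scheme$reference
  if (any(ref <= 0)) {
    stop("reference table contains non-positive entries")
  }
  factor_panel(
    donor_id = donor_id, group = group, sex = sex,
    genotype_20210 = genotype_20210,
    FII_pct = 100 * profile[["FII"]] / ref[["FII"]],
    FV_pct = 100 * profile[["FV"]] / ref[["FV"]],
    FVII_pct = 100 * (profile[["FVII"]] + profile[["FVIIa"]]) / ref[["FVII"]],
    FVIII_pct = 100 * profile[["FVIII"]] / ref[["FVIII"]],
    FIX_pct = 100 * profile[["FIX"]] / ref[["FIX"]],
    FX_pct = 100 * profile[["FX"]] / ref[["FX"]],
    AT_pct = 100 * profile[["AT"]] / ref[["AT"]],
    TF_pM = profile[["TF"]] * 1e12,
    TFPI_U_per_mL = profile[["TFPI"]] / ref[["TFPI"]])
}

#' Read a cohort CSV
#'
#' Expects the standard header `donor_id,group,sex,genotype_20210,FII_pct,
#' FV_pct,FVII_pct,FVIII_pct,FIX_pct,FX_pct,AT_pct,TF_pM,TFPI_U_per_mL`
#' (UTF-8, dot decimal separator).
#'
#' @param path CSV file path.
#' @return A cohort data frame; donor IDs are checked for uniqueness and all
#'   rows pass factor-panel validation.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

validate_cohort <- function(cohort) {
  needed <- c("donor_id", "group", "sex", "genotype_20210",
              panel_factor_columns())
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cohort$donor_id)) {
    stop("cohort contains duplicate donor_id values")
  }
  for (col in panel_factor_columns()) {
    v <- cohort[[col]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("cohort column '", col, "' contains negative or non-finite values")
    }
  }
  invisible(cohort)
}
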