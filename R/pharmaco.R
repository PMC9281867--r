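#' Construct an anticoagulant specification
#'
#' Three drug classes are modelled. A vitamin K antagonist (warfarin) acts at
#' equilibrium by scaling the vitamin-K-dependent factors (FII, FVII/FVIIa,
#' FIX, FX) to a fraction of their original level. Direct FXa and FIIa
#' inhibitors are modelled kinetically as a reversible-binding species added
#' to the reaction network at a fixed plasma dose.
#'
#' @param kind `"vitamin_k_antagonist"`, `"xa_inhibitor"` or
#'   `"iia_inhibitor"`.
#' @param dose Plasma concentration of a direct inhibitor, M. Ignored for the
#'   vitamin K antagonist.
#' @param fraction Residual fraction of vitamin-K-dependent factor levels in
#'   (0, 1]. Ignored for direct inhibitors.
#' @param kon,koff Binding on-rate (M-1 s-1) and off-rate (s-1) of a direct
#'   inhibitor.
#' @param bind_complexed If `TRUE`, the inhibitor also binds its target
#'   inside the prothrombinase complex (FXa inhibitor) or as meizothrombin
#'   (FIIa inhibitor). Default `FALSE`.
#' @param name Label used in reports.
#' @return Object of class `drug_spec`.
#' @export
drug_spec <- function(kind = c("vitamin_k_antagonist", "xa_inhibitor",
                               "iia_inhibitor"),
                      dose = 0, fraction = 0.33, kon = 1e8, koff = 0.04,
                      bind_complexed = FALSE, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "vitamin_k_antagonist") {
    if (!(fraction > 0 && fraction <= 1)) {
      stop("fraction must be in (0, 1]")
    }
  } else {
    if (dose < 0) stop("dose must be >= 0")
    if (kon <= 0 || koff <= 0) stop("on/off rates must be positive")
  }
  structure(list(kind = kind, dose = dose, fraction = fraction, kon = kon,
                 koff = koff, bind_complexed = bind_complexed,
                 name = if (is.null(name)) kind else name),
            class = "drug_spec")
}

#' Default anticoagulant specifications from the parameter file
#'
#' Standard therapeutic exposure: warfarin as a scaling of
#' vitamin-K-dependent factors to 33%, a direct FXa inhibitor
#' (rivaroxaban-like) at 6 nM, and a direct thrombin inhibitor
#' (dabigatran-like) at 0.3 uM.
#'
#' @param scheme A `coag_scheme`.
#' @return Named list of `drug_spec` objects.
#' @export
default_drugs <- function(scheme) {
  out <- list()
  for (nm in names(scheme$drugs)) {
    d <- scheme$drugs[[nm]]
    out[[nm]] <- drug_spec(
      kind = d$kind,
      dose = if (!is.null(d$dose_M)) as.numeric(d$dose_M) else 0,
      fraction = if (!is.null(d$fraction)) as.numeric(d$fraction) else 0.33,
      kon = if (!is.null(d$kon)) as.numeric(d$kon) else 1e8,
      koff = if (!is.null(d$koff)) as.numeric(d$koff) else 0.04,
      bind_complexed = isTRUE(d$bind_complexed),
      name = nm)
  }
  out
}

#' Apply a vitamin K antagonist to a donor profile
#'
#' Scales the vitamin-K-dependent factors FII, FVII (and its FVIIa split),
#' FIX and FX by `fraction`; all other initial conditions are untouched.
#'
#' @param profile A `donor_profile`.
#' @param fraction Residual fraction in (0, 1] (default 0.33, the standard
#'   therapeutic level).
#' @return The scaled `donor_profile`.
#' @export
apply_vka <- function(profile, fraction = 0.33) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]")
  }
  vkd <- c("FII", "FVII", "FVIIa", "FIX", "FX")
  profile[vkd] <- profile[vkd] * fraction
  profile
}

#' Extend the reaction scheme with a direct inhibitor
#'
#' Adds a drug species `D` and a drug-target complex with reversible binding
#' target + D <-> target:D at the specification's on/off rates. The FXa
#' inhibitor binds free FXa (and, if `bind_complexed`, prothrombinase-bound
#' FXa); the FIIa inhibitor binds free FIIa (and, if `bind_complexed`,
#' meizothrombin). The drug forms its own conserved lineage.
#'
#' @param scheme A `coag_scheme`.
#' @param spec A direct-inhibitor `drug_spec`.
#' @return A list: `scheme` (extended `coag_scheme`) and `dose_species`
#'   (named numeric: the drug's initial concentration to merge into the
#'   state).
#' @export
extend_scheme_with_inhibitor <- function(scheme, spec) {
  if (!inherits(spec, "drug_spec") || spec$kind == "vitamin_k_antagonist") {
    stop("spec must be a direct-inhibitor drug_spec ",
         "(xa_inhibitor or iia_inhibitor)")
  }
  targets <- switch(spec$kind,
    xa_inhibitor = if (spec$bind_complexed) c("FXa", "Xa:Va") else "FXa",
    iia_inhibitor = if (spec$bind_complexed) c("FIIa", "mIIa") else "FIIa")

  ext <- scheme
  drug <- "D"
  if (drug %in% ext$species) {
    stop("scheme already contains a drug species")
  }
  ext$species <- c(ext$species, drug)
  kon_id <- "k_drug_on"
  koff_id <- "k_drug_off"
  ext$rates[[kon_id]] <- spec$kon
  ext$rates[[koff_id]] <- spec$koff
  ext$rate_units[[kon_id]] <- "M-1 s-1"
  ext$rate_units[[koff_id]] <- "s-1"
  ext$lineages$drug <- stats::setNames(1, drug)

  for (target in targets) {
    complex <- paste0(target, ":D")
    ext$species <- c(ext$species, complex)
    ext$reactions <- c(ext$reactions, list(
      list(reactants = c(target, drug), products = complex, k = kon_id,
           kind = "binding"),
      list(reactants = complex, products = c(target, drug), k = koff_id,
           kind = "dissociation")))
    # the complex carries the target's lineages and the drug lineage
    for (lin in names(ext$lineages)) {
      w <- ext$lineages[[lin]]
      if (target %in% names(w)) {
        w[[complex]] <- w[[target]]
        ext$lineages[[lin]] <- w
      }
    }
    ext$lineages$drug[[complex]] <- 1
  }

  ext$matrices <- scheme_matrices(ext)
  audit <- audit_conservation(ext)
  if (!all(audit$conserved)) {
    stop("drug extension broke lineage conservation")
  }
  list(scheme = ext, dose_species = stats::setNames(spec$dose, drug))
}

#' Simulate a donor with an anticoagulant applied
#'
#' @param profile A `donor_profile`.
#' @param spec A `drug_spec`.
#' @param scheme A `coag_scheme`.
#' @param ... Passed to [simulate_donor()].
#' @return A `coag_trajectory`.
#' @export
simulate_with_drug <- function(profile, spec, scheme, ...) {
  if (spec$kind == "vitamin_k_antagonist") {
    return(simulate_donor(apply_vka(profile, spec$fraction), scheme, ...))
  }
  ext <- extend_scheme_with_inhibitor(scheme, spec)
  state <- c(unclass(profile), ext$dose_species)
  simulate_donor(state, ext$scheme, ...)
}

#' Predicted effect of an anticoagulant on one donor
#'
#' Simulates the donor undrugged and drugged and reports the percent
#' reduction in peak free thrombin, 100 (peak0 - peak_d) / peak0, and the
#' percent change in time to peak, 100 (t_d - t0) / t0.
#'
#' @param panel A `factor_panel` (or cohort row), or a `donor_profile`.
#' @param spec A `drug_spec`.
#' @param scheme A `coag_scheme`.
#' @param ... Passed to [simulate_donor()].
#' @return One-row data frame: `drug`, `pct_peak_reduction`,
#'   `pct_time_to_peak_change`, `drugged_peak_M`, `drugged_time_to_peak_s`,
#'   `undrugged_peak_M`, `undrugged_time_to_peak_s`, `dose_M`, `undefined`
#'   (`TRUE` when the undrugged peak is zero).
#' @export
drug_effect <- function(panel, spec, scheme, ...) {
  profile <- if (inherits(panel, "donor_profile") ||
                 (is.numeric(panel) && !is.null(names(panel)))) {
    panel
  } else {
    panel_to_profile(panel, scheme)
  }
  base <- simulate_donor(profile, scheme, ...)
  drugged <- simulate_with_drug(profile, spec, scheme, ...)
  s0 <- summarize_trajectory(base, scheme)
  sd_ <- summarize_trajectory(drugged, scheme)

  undefined <- s0$peak_FIIa_M <= 0
  data.frame(
    drug = spec$name,
    pct_peak_reduction = if (undefined) NA_real_ else
      100 * (s0$peak_FIIa_M - sd_$peak_FIIa_M) / s0$peak_FIIa_M,
    pct_time_to_peak_change = if (undefined) NA_real_ else
      100 * (sd_$time_to_peak_FIIa_s - s0$time_to_peak_FIIa_s) /
        s0$time_to_peak_FIIa_s,
    drugged_peak_M = sd_$peak_FIIa_M,
    drugged_time_to_peak_s = sd_$time_to_peak_FIIa_s,
    undrugged_peak_M = s0$peak_FIIa_M,
    undrugged_time_to_peak_s = s0$time_to_peak_FIIa_s,
    dose_M = if (spec$kind == "vitamin_k_antagonist") NA_real_ else spec$dose,
    undefined = undefined,
    stringsAsFactors = FALSE)
}

#' Drug effects across a cohort
#'
#' @param cohort Cohort data frame.
#' @param drugs Named list of `drug_spec`s (default: [default_drugs()]).
#' @param scheme A `coag_scheme`.
#' @param ... Passed to [simulate_donor()].
#' @return Data frame with one row per donor x drug: donor metadata plus the
#'   [drug_effect()] columns.
#' @export
cohort_drug_effects <- function(cohort, drugs = NULL, scheme, ...) {
  validate_cohort(cohort)
  if (is.null(drugs)) {
    drugs <- default_drugs(scheme)
  }
  out <- vector("list", nrow(cohort) * length(drugs))
  idx <- 1
  for (i in seq_len(nrow(cohort))) {
    panel <- cohort[i, , drop = FALSE]
    profile <- panel_to_profile(panel, scheme)
    base <- summarize_trajectory(simulate_donor(profile, scheme, ...), scheme)
    for (d in drugs) {
      drugged <- summarize_trajectory(
        simulate_with_drug(profile, d, scheme, ...), scheme)
      undefined <- base$peak_FIIa_M <= 0
      out[[idx]] <- data.frame(
        donor_id = panel$donor_id,
        drug = d$name,
        pct_peak_reduction = if (undefined) NA_real_ else
          100 * (base$peak_FIIa_M - drugged$peak_FIIa_M) / base$peak_FIIa_M,
        pct_time_to_peak_change = if (undefined) NA_real_ else
          100 * (drugged$time_to_peak_FIIa_s - base$time_to_peak_FIIa_s) /
            base$time_to_peak_FIIa_s,
        drugged_peak_M = drugged$peak_FIIa_M,
        drugged_time_to_peak_s = drugged$time_to_peak_FIIa_s,
        undrugged_peak_M = base$peak_FIIa_M,
        undrugged_time_to_peak_s = base$time_to_peak_FIIa_s,
        undefined = undefined,
        stringsAsFactors = FALSE)
      idx <- idx + 1
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
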