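#' Normal range from control-group levels
#'
#' The study convention: mean plus/minus two sample standard deviations.
#'
#' @param values Numeric vector of control-group factor levels (n >= 2).
#' @return Named numeric vector `c(low, high)` with attributes `mean` and
#'   `sd`.
#' @export
normal_range <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("normal range requires at least two values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  structure(c(low = m - 2 * s, high = m + 2 * s), mean = m, sd = s)
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance by default (Welch optional), two-sided. Accepts either raw
#' samples (`a`, `b`) or summary statistics (`n1`, `m1`, `s1`, `n2`, `m2`,
#' `s2`) so printed cohort tables can be re-tested.
#'
#' @param a,b Numeric samples (each n >= 2), or `NULL` when using summary
#'   statistics.
#' @param n1,m1,s1,n2,m2,s2 Group sizes, means and sample SDs for
#'   summary-statistic mode.
#' @param welch Use Welch's unequal-variance test (raw-sample mode only).
#' @return List: `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
compare_groups <- function(a = NULL, b = NULL, n1 = NULL, m1 = NULL,
                           s1 = NULL, n2 = NULL, m2 = NULL, s2 = NULL,
                           welch = FALSE) {
  if (!is.null(a) && !is.null(b)) {
    if (length(a) < 2 || length(b) < 2) {
      stop("each group needs at least two values")
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                    mean_diff = 0))
      }
      return(list(t = Inf * sign(mean(a) - mean(b)),
                  df = length(a) + length(b) - 2, p = 0,
                  mean_diff = mean(a) - mean(b)))
    }
    ht <- stats::t.test(a, b, var.equal = !welch)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, mean_diff = mean(a) - mean(b)))
  }
  if (any(vapply(list(n1, m1, s1, n2, m2, s2), is.null, TRUE))) {
    stop("supply either raw samples a and b, or all six summary statistics")
  }
  if (n1 < 2 || n2 < 2) {
    stop("each group needs n >= 2")
  }
  # pooled-variance t from summary statistics
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, mean_diff = 0))
    }
    return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p = 0,
                mean_diff = m1 - m2))
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_diff = m1 - m2)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return List: `statistic`, `df`, `p`.
#' @export
compare_categorical <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has a zero marginal")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Carriage frequency as a percentage
#'
#' @param carriers Number of carriers.
#' @param n Group size (> 0).
#' @return 100 * carriers / n.
#' @export
carriage_frequency <- function(carriers, n) {
  if (n <= 0) stop("n must be positive")
  if (carriers < 0 || carriers > n) {
    stop("carriers must be between 0 and n")
  }
  100 * carriers / n
}

# balanced tertile sizes: remainder goes to the lower tertiles
tertile_sizes <- function(n) {
  base <- n %/% 3
  rem <- n %% 3
  base + c(rem >= 1, rem >= 2, 0)
}

#' Rank-based tertile assignment
#'
#' Sorts donors by the key (ties broken by donor id), then cuts into three
#' contiguous groups whose sizes differ by at most one; any remainder goes to
#' the lower tertiles.
#'
#' @param values Numeric key (e.g. peak thrombin), one per donor.
#' @param ids Donor identifiers (used as deterministic tie-break and as the
#'   names of the result).
#' @return Factor with levels `low`, `medium`, `high`, named by `ids`, with
#'   attribute `degenerate = TRUE` when all key values are equal.
#' @export
tertile_stratify <- function(values, ids = names(values)) {
  if (is.null(ids)) {
    ids <- as.character(seq_along(values))
  }
  keep <- is.finite(values)
  if (sum(keep) < 3) {
    stop("tertile stratification needs at least three finite key values")
  }
  v <- values[keep]
  id <- as.character(ids)[keep]
  ord <- order(v, id)
  n <- length(v)
  sizes <- tertile_sizes(n)
  lev <- rep(c("low", "medium", "high"), times = sizes)
  out <- factor(character(n), levels = c("low", "medium", "high"))
  out[ord] <- lev
  names(out) <- id
  attr(out, "degenerate") <- length(unique(v)) == 1
  out
}

#' Heatmap data matrix for cohort stratification
#'
#' Builds the stratification table: donors ordered by thrombin tertile (then
#' key value, then donor id), per-factor tertiles of the raw assay levels,
#' sex and group annotations, and per-drug effect columns when drug effects
#' are supplied. Emitted as data; rendering is left to the caller.
#'
#' @param cohort Cohort data frame.
#' @param summaries Output of [cohort_summaries()].
#' @param key Summary column used for stratification (default
#'   `"peak_FIIa_M"`; set `"thrombin_AUC_Ms"` to stratify on thrombin AUC).
#' @param drug_effects Optional output of [cohort_drug_effects()].
#' @return Data frame with one row per donor: `donor_id`, `thrombin_tertile`,
#'   `key_value`, tertile columns `<factor>_tertile` for the nine measured
#'   factors, `sex`, `group`, and, per drug, `<drug>_pct_peak_reduction` and
#'   `<drug>_pct_time_to_peak_change`.
#' @export
heatmap_matrix <- function(cohort, summaries, key = "peak_FIIa_M",
                           drug_effects = NULL) {
  validate_cohort(cohort)
  if (is.null(summaries[[key]])) {
    stop("summaries lack stratification key '", key, "'")
  }
  keyv <- stats::setNames(summaries[[key]], summaries$donor_id)
  keyv <- keyv[cohort$donor_id]
  assignment <- tertile_stratify(keyv, cohort$donor_id)

  out <- data.frame(donor_id = cohort$donor_id,
                    thrombin_tertile = as.character(assignment[cohort$donor_id]),
                    key_value = unname(keyv),
                    stringsAsFactors = FALSE)
  for (f in names(driver_factors())) {
    col <- driver_factors()[[f]]
    out[[paste0(f, "_tertile")]] <-
      as.character(tertile_stratify(cohort[[col]], cohort$donor_id))
  }
  out$sex <- cohort$sex
  out$group <- cohort$group

  if (!is.null(drug_effects)) {
    for (d in unique(drug_effects$drug)) {
      sub <- drug_effects[drug_effects$drug == d, , drop = FALSE]
      i <- match(out$donor_id, sub$donor_id)
      out[[paste0(d, "_pct_peak_reduction")]] <- sub$pct_peak_reduction[i]
      out[[paste0(d, "_pct_time_to_peak_change")]] <-
        sub$pct_time_to_peak_change[i]
    }
  } else {
    warning("no drug effects supplied; drug columns omitted")
  }

  tert_rank <- match(out$thrombin_tertile, c("high", "medium", "low"))
  out <- out[order(tert_rank, -out$key_value, out$donor_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate measured factor levels with predicted drug effects
#'
#' Pearson correlation (with two-sided p) between each measured factor and
#' each drug's predicted effect on the chosen endpoint, across donors.
#'
#' @param cohort Cohort data frame.
#' @param drug_effects Output of [cohort_drug_effects()].
#' @param endpoint `"peak"` (percent peak reduction) or `"time_to_peak"`
#'   (percent time-to-peak change).
#' @return Data frame: `factor`, `drug`, `endpoint`, `r`, `p`, `n`,
#'   `undefined` (`TRUE` for zero-variance factors).
#' @export
correlate_factors_with_effects <- function(cohort, drug_effects,
                                           endpoint = c("peak",
                                                        "time_to_peak")) {
  endpoint <- match.arg(endpoint)
  validate_cohort(cohort)
  ycol <- if (endpoint == "peak") "pct_peak_reduction" else
    "pct_time_to_peak_change"
  rows <- list()
  for (d in unique(drug_effects$drug)) {
    sub <- drug_effects[drug_effects$drug == d, , drop = FALSE]
    i <- match(cohort$donor_id, sub$donor_id)
    y <- sub[[ycol]][i]
    for (f in names(driver_factors())) {
      x <- cohort[[driver_factors()[[f]]]]
      keep <- is.finite(x) & is.finite(y)
      n <- sum(keep)
      if (n < 3) {
        stop("correlation requires at least three donors")
      }
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          factor = f, drug = d, endpoint = endpoint, r = NA_real_,
          p = NA_real_, n = n, undefined = TRUE, stringsAsFactors = FALSE)
        next
      }
      ht <- stats::cor.test(x[keep], y[keep], method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        factor = f, drug = d, endpoint = endpoint,
        r = unname(ht$estimate), p = ht$p.value, n = n, undefined = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
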