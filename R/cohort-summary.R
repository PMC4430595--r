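#' Group summary statistics
#'
#' Arithmetic mean and sample (n-1) standard deviation, the form in which
#' the study tables report every pharmacokinetic parameter. The SD is
#' reported as missing for a single observation.
#'
#' @param values Numeric vector (non-empty).
#' @return List with `n`, `mean`, `sd`.
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no data: empty group")
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_)
}

#' Tukey fence outlier screening
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` using Tukey's hinges
#' (median-split halves, the `fivenum` convention). Flagged values are
#' annotated only, never removed from any analysis. The flag set is
#' invariant under positive affine transformation of the data.
#'
#' @param values Numeric vector.
#' @return Integer indices of flagged values (empty when n < 4, with a
#'   warning).
#' @export
tukey_outliers <- function(values) {
  if (length(values) < 4) {
    warning("fewer than 4 values: outlier screen not applied")
    return(integer(0))
  }
  f <- stats::fivenum(values)
  iqr <- f[4] - f[2]
  which(values < f[2] - 1.5 * iqr | values > f[4] + 1.5 * iqr)
}

#' Percent increase in mean exposure relative to normal renal function
#'
#' For each impaired stratum, `100 * (mean / mean_normal - 1)` computed from
#' the arithmetic group means; `pct_rounded` carries the nearest-integer
#' value used for report display.
#'
#' @param group_means Named numeric vector of stratum mean AUC (must include
#'   `normal` with a positive mean).
#' @return Data frame `stratum, ratio_vs_normal, pct_increase, pct_rounded`
#'   for every non-normal stratum, in the input order.
#' @export
percent_increase_vs_normal <- function(group_means) {
  if (!"normal" %in% names(group_means) || group_means[["normal"]] <= 0)
    stop("missing reference: normal stratum with positive mean required")
  ref <- group_means[["normal"]]
  strata <- setdiff(names(group_means), "normal")
  ratio <- unname(group_means[strata]) / ref
  data.frame(stratum = strata, ratio_vs_normal = ratio,
             pct_increase = 100 * (ratio - 1),
             pct_rounded = round(100 * (ratio - 1)),
             stringsAsFactors = FALSE)
}

#' Percent reduction in mean clearance relative to normal renal function
#'
#' `100 * (1 - mean / mean_normal)` for each impaired stratum.
#'
#' @param group_means Named numeric vector of stratum mean clearance (must
#'   include `normal` with a positive mean).
#' @return Data frame `stratum, pct_reduction`.
#' @export
percent_reduction_vs_normal <- function(group_means) {
  if (!"normal" %in% names(group_means) || group_means[["normal"]] <= 0)
    stop("missing reference: normal stratum with positive mean required")
  ref <- group_means[["normal"]]
  strata <- setdiff(names(group_means), "normal")
  data.frame(stratum = strata,
             pct_reduction = 100 * (1 - unname(group_means[strata]) / ref),
             stringsAsFactors = FALSE)
}

#' Regression of total clearance on creatinine clearance
#'
#' Ordinary least squares of absolute total body clearance (mL/h) on
#' un-normalised Cockcroft-Gault creatinine clearance (mL/min), the
#' relationship that links drug elimination to renal function across the
#' whole range of renal impairment. r-squared is the squared Pearson
#' correlation.
#'
#' @param clcr Creatinine clearance values, mL/min (>= 3, non-constant).
#' @param cl Absolute total clearance values, mL/h.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
cl_vs_clcr_regression <- function(clcr, cl) {
  if (length(clcr) < 3 || length(cl) != length(clcr))
    stop("insufficient data: need at least 3 matched pairs")
  if (stats::sd(clcr) == 0)
    stop("degenerate fit: creatinine clearance has zero variance")
  fit <- stats::lm(cl ~ clcr)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = stats::cor(clcr, cl)^2, n = length(clcr))
}

#' Stratum-level parameter summaries with outlier annotation
#'
#' Summarises each parameter by stratum (mean, SD, n) and annotates Tukey
#' fence outliers; outliers are flagged, never excluded.
#'
#' @param results Data frame with a `stratum` column and a `subject_id`
#'   column.
#' @param parameters Character vector of numeric columns to summarise.
#' @return Data frame `stratum, parameter, n, mean, sd, outlier_ids`
#'   (comma-separated subject ids, empty when none).
#' @export
summarize_by_stratum <- function(results, parameters) {
  strata <- unique(results$stratum)
  out <- list()
  for (st in strata) {
    sub <- results[results$stratum == st, ]
    for (p in parameters) {
      v <- sub[[p]]
      s <- summarize_group(v)
      fl <- suppressWarnings(tukey_outliers(v))
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, parameter = p, n = s$n, mean = s$mean, sd = s$sd,
        outlier_ids = paste(sub$subject_id[fl], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
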