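#' Quantifiable observations of a concentration profile
#'
#' Applies the below-limit-of-quantification policy: a pre-dose (time 0) BLQ
#' sample is set to 0 and retained as the curve origin; every other BLQ
#' sample (embedded or trailing) is excluded, so that only measurable
#' concentrations enter the parameter calculations.
#'
#' @param time,conc,blq Parallel vectors: time (h), concentration (ug/mL,
#'   may be NA when BLQ) and BLQ indicator (0/1 or logical).
#' @return Data frame `time`, `conc` sorted by time.
#' @keywords internal
quantifiable <- function(time, conc, blq = NULL) {
  if (is.null(blq)) blq <- rep(FALSE, length(time))
  blq <- as.logical(blq)
  keep <- !blq | time == 0
  time <- time[keep]; conc <- conc[keep]; blq <- blq[keep]
  conc[blq & time == 0] <- 0
  ord <- order(time)
  data.frame(time = time[ord], conc = conc[ord])
}

#' Peak concentration and its time
#'
#' Maximum observed concentration; ties resolve to the earliest time.
#'
#' @param time,conc,blq As in [quantifiable()].
#' @return List with `cmax` (ug/mL) and `tmax` (h).
#' @export
cmax_tmax <- function(time, conc, blq = NULL) {
  q <- quantifiable(time, conc, blq)
  q <- q[q$conc > 0 | q$time > 0, , drop = FALSE]
  if (!nrow(q)) stop("no data: profile has no quantifiable observation")
  i <- which.max(q$conc)           # which.max returns the first (earliest) max
  list(cmax = q$conc[i], tmax = q$time[i])
}

#' Terminal elimination rate constant
#'
#' Log-linear least-squares estimation of the terminal slope. Every
#' candidate window of at least `min_points` quantifiable observations that
#' ends at the last quantifiable sample and starts strictly after the peak
#' is fitted by `lm(log C ~ t)`; the window with the largest adjusted
#' r-squared wins, ties (within 1e-10) going to the window with more points.
#' This mirrors the automatic best-fit selection of standard NCA software.
#'
#' @param time,conc,blq As in [quantifiable()].
#' @param min_points Minimum window size (default 3).
#' @return List with `lambda_z` (1/h), `n_points`, `adj_r2`, `t_first`
#'   (window start time).
#' @export
select_lambda_z <- function(time, conc, blq = NULL, min_points = 3) {
  q <- quantifiable(time, conc, blq)
  q <- q[q$conc > 0, , drop = FALSE]
  if (nrow(q) < 2) stop("insufficient terminal data: fewer than 3 post-peak points")
  imax <- which.max(q$conc)
  post <- q[q$time > q$time[imax], , drop = FALSE]
  n <- nrow(post)
  if (n < min_points) {
    if (imax == nrow(q) && nrow(q) >= min_points)
      stop("no terminal decline: concentrations rise to the last observation")
    stop("insufficient terminal data: fewer than ", min_points, " post-peak points")
  }
  best <- NULL
  for (start in seq_len(n - min_points + 1)) {
    w <- post[start:n, , drop = FALSE]
    fit <- stats::lm(log(w$conc) ~ w$time)
    slope <- stats::coef(fit)[2]
    if (!is.finite(slope) || slope >= 0) next
    r2 <- stats::cor(log(w$conc), w$time)^2
    k <- nrow(w)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-10 ||
        (abs(adj - best$adj_r2) <= 1e-10 && k > best$n_points))
      best <- list(lambda_z = -unname(slope), n_points = k, adj_r2 = adj,
                   t_first = w$time[1])
  }
  if (is.null(best))
    stop("no terminal decline: no candidate window has a negative slope")
  best
}

#' Area under the curve to the last quantifiable sample
#'
#' Trapezoidal integration. `"linear"` uses the linear trapezoid on every
#' panel; `"lin_up_log_down"` uses the logarithmic trapezoid
#' \eqn{\Delta t (C_1 - C_2)/\ln(C_1/C_2)} on strictly declining panels with
#' both concentrations positive, falling back to linear on rising, flat or
#' zero-bounded panels.
#'
#' @param time,conc,blq As in [quantifiable()].
#' @param method `"linear"` (default) or `"lin_up_log_down"`.
#' @return AUC in ug.h/mL.
#' @export
auc_0_t <- function(time, conc, blq = NULL, method = c("linear", "lin_up_log_down")) {
  method <- match.arg(method)
  q <- quantifiable(time, conc, blq)
  if (nrow(q) < 2) stop("no data: need at least 2 quantifiable observations")
  total <- 0
  for (i in seq_len(nrow(q) - 1)) {
    dt <- q$time[i + 1] - q$time[i]
    c1 <- q$conc[i]; c2 <- q$conc[i + 1]
    panel <- if (method == "lin_up_log_down" && c2 < c1 && c2 > 0)
      dt * (c1 - c2) / log(c1 / c2)
    else
      dt * (c1 + c2) / 2
    total <- total + panel
  }
  total
}

#' Extrapolate AUC to infinity
#'
#' \deqn{AUC_{0-\infty} = AUC_{0-t} + C_{last}/\lambda_z}
#' using the observed last quantifiable concentration.
#'
#' @param auc0t AUC to the last quantifiable sample, ug.h/mL.
#' @param c_last Last quantifiable concentration, ug/mL (> 0).
#' @param lambda_z Terminal rate constant, 1/h (> 0).
#' @return List with `auc_0_inf` and `pct_extrapolated` (percent of the
#'   total area contributed by the tail, always < 100).
#' @export
auc_0_inf <- function(auc0t, c_last, lambda_z) {
  if (lambda_z <= 0 || c_last <= 0)
    stop("invalid input: lambda_z and c_last must be positive")
  tail <- c_last / lambda_z
  total <- auc0t + tail
  list(auc_0_inf = total, pct_extrapolated = 100 * tail / total)
}

#' First-moment area and mean residence time
#'
#' AUMC to the last sample by the linear trapezoid on t*C, plus the analytic
#' tail \eqn{C_{last}(t_{last}/\lambda_z + 1/\lambda_z^2)}. The mean
#' residence time subtracts half the infusion duration to correct the
#' zero-order input:
#' \deqn{MRT = AUMC_{0-\infty}/AUC_{0-\infty} - t_{inf}/2.}
#'
#' @param time,conc,blq As in [quantifiable()].
#' @param lambda_z Terminal rate constant, 1/h.
#' @param t_inf Infusion duration, h (0 for a bolus).
#' @param auc0inf AUC to infinity; computed from the same profile when NULL.
#' @param method AUC method used for the AUC-to-infinity fallback.
#' @return List with `aumc_0_inf` (ug.h^2/mL) and `mrt` (h).
#' @export
aumc_mrt <- function(time, conc, blq = NULL, lambda_z, t_inf = 0,
                     auc0inf = NULL, method = "linear") {
  q <- quantifiable(time, conc, blq)
  if (nrow(q) < 2) stop("no data: need at least 2 quantifiable observations")
  tc <- q$time * q$conc
  aumc_t <- sum(diff(q$time) * (utils::head(tc, -1) + utils::tail(tc, -1)) / 2)
  last <- nrow(q)
  c_last <- q$conc[last]; t_last <- q$time[last]
  aumc_inf <- aumc_t + c_last * (t_last / lambda_z + 1 / lambda_z^2)
  if (is.null(auc0inf)) {
    a0t <- auc_0_t(q$time, q$conc, method = method)
    auc0inf <- auc_0_inf(a0t, c_last, lambda_z)$auc_0_inf
  }
  list(aumc_0_inf = aumc_inf, mrt = aumc_inf / auc0inf - t_inf / 2)
}

#' Total body clearance from dose and exposure
#'
#' \deqn{CL = 1000 \times dose_{mg/kg} / AUC_{0-\infty}}
#' (the factor 1000 converts mg/kg to ug/kg so that ug/kg divided by
#' ug.h/mL gives mL/h/kg).
#'
#' @param dose_per_kg Dose, mg/kg.
#' @param auc0inf AUC to infinity, ug.h/mL (> 0).
#' @return Clearance, mL/h/kg.
#' @export
clearance <- function(dose_per_kg, auc0inf) {
  if (auc0inf <= 0) stop("invalid input: AUC must be positive")
  1000 * dose_per_kg / auc0inf
}

#' Volume of distribution at steady state
#'
#' \deqn{V_{ss} = CL \times MRT}
#'
#' @param cl Clearance, mL/h/kg.
#' @param mrt Mean residence time, h.
#' @return Vss, mL/kg.
#' @export
vss <- function(cl, mrt) cl * mrt

#' Full non-compartmental analysis of one profile
#'
#' Composes peak, terminal-slope, AUC, moment and clearance calculations
#' into the standard single-dose parameter set. Only measurable
#' concentrations are used (see [quantifiable()] for the BLQ policy).
#'
#' @param time,conc,blq The observed profile.
#' @param dose_per_kg Delivered dose, mg/kg.
#' @param t_inf Infusion duration, h.
#' @param method AUC method, see [auc_0_t()].
#' @return One-row data frame: `cmax, tmax, lambda_z, n_lambda_points,
#'   adj_r2, t_half, auc_0_t, auc_0_inf, pct_extrapolated, aumc_0_inf, mrt,
#'   cl, vss`.
#' @export
run_nca <- function(time, conc, blq = NULL, dose_per_kg, t_inf = 1,
                    method = "linear") {
  pk <- cmax_tmax(time, conc, blq)
  lz <- select_lambda_z(time, conc, blq)
  a0t <- auc_0_t(time, conc, blq, method = method)
  q <- quantifiable(time, conc, blq)
  q <- q[q$conc > 0, , drop = FALSE]
  c_last <- q$conc[nrow(q)]
  ainf <- auc_0_inf(a0t, c_last, lz$lambda_z)
  mom <- aumc_mrt(time, conc, blq, lambda_z = lz$lambda_z, t_inf = t_inf,
                  auc0inf = ainf$auc_0_inf, method = method)
  cl_val <- clearance(dose_per_kg, ainf$auc_0_inf)
  data.frame(cmax = pk$cmax, tmax = pk$tmax,
             lambda_z = lz$lambda_z, n_lambda_points = lz$n_points,
             adj_r2 = lz$adj_r2, t_half = log(2) / lz$lambda_z,
             auc_0_t = a0t, auc_0_inf = ainf$auc_0_inf,
             pct_extrapolated = ainf$pct_extrapolated,
             aumc_0_inf = mom$aumc_0_inf, mrt = mom$mrt,
             cl = cl_val, vss = vss(cl_val, mom$mrt))
}

#' Non-compartmental analysis of a study concentration table
#'
#' Runs [run_nca()] for every subject/analyte in a long-format
#' concentration table, attaching dose and stratum metadata.
#'
#' @param concentrations Data frame `subject_id, analyte, time_h,
#'   conc_ug_ml, blq`.
#' @param truth Per subject/analyte metadata with `subject_id, analyte,
#'   dose_mg_kg` and optionally `stratum`, `weight_kg` (the simulator's
#'   `truth` table, or an equivalent dosing table for real data).
#' @param t_inf Infusion duration, h.
#' @param method AUC method.
#' @return Data frame, one row per subject/analyte; subjects whose profile
#'   fails (e.g. all BLQ) are skipped with a warning naming the subject.
#' @export
run_nca_table <- function(concentrations, truth, t_inf = 1, method = "linear") {
  out <- list()
  keys <- unique(concentrations[c("subject_id", "analyte")])
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; an <- keys$analyte[i]
    rows <- concentrations[concentrations$subject_id == sid &
                             concentrations$analyte == an, ]
    meta <- truth[truth$subject_id == sid & truth$analyte == an, ][1, ]
    res <- tryCatch(
      run_nca(rows$time_h, rows$conc_ug_ml, rows$blq,
              dose_per_kg = meta$dose_mg_kg, t_inf = t_inf, method = method),
      error = function(e) {
        warning("NCA failed for subject ", sid, " (", an, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    res <- cbind(data.frame(subject_id = sid, analyte = an,
                            stringsAsFactors = FALSE), res)
    if (!is.null(meta$stratum)) res$stratum <- meta$stratum
    if (!is.null(meta$weight_kg)) res$weight_kg <- meta$weight_kg
    out[[length(out) + 1L]] <- res
  }
  if (!length(out)) stop("no data: NCA failed for every profile")
  do.call(rbind, out)
}
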