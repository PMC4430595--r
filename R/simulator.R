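#' Plasma sampling schedule for a study design
#'
#' Study A samples pre-infusion and at 1, 2, 4, 6, 8, 12, 24, 36 and 48 h
#' after the start of the 1-h infusion, extended to 72 and 96 h for subjects
#' with severe impairment or ESRD. Study B samples pre-infusion and at 0.5,
#' 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 24, 36, 48, 60, 72, 84 and 96 h. All
#' times are hours after the start of infusion.
#'
#' @param study `"A"` or `"B"`.
#' @param stratum Renal stratum; controls the study-A late extension.
#' @return Numeric vector of sampling times (h), starting at 0.
#' @export
sampling_schedule <- function(study = c("A", "B"), stratum = "normal") {
  study <- match.arg(study)
  if (study == "A") {
    times <- c(0, 1, 2, 4, 6, 8, 12, 24, 36, 48)
    if (stratum %in% c("severe", "esrd")) times <- c(times, 72, 96)
    times
  } else {
    c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 24, 36, 48, 60, 72, 84, 96)
  }
}

#' Urine collection intervals of the study-B design
#'
#' Contiguous intervals 0-6, 6-12, 12-24, 24-36, 36-48, 48-60, 60-72, 72-84
#' and 84-96 h after the start of infusion.
#'
#' @return Data frame with columns `start_h`, `end_h`.
#' @export
urine_intervals <- function() {
  bounds <- c(0, 6, 12, 24, 36, 48, 60, 72, 84, 96)
  data.frame(start_h = bounds[-length(bounds)], end_h = bounds[-1])
}

#' Virtual-cohort simulation configuration
#'
#' Bundles every tunable of the cohort simulator with defaults that emulate
#' the two single-dose telavancin renal-impairment studies: five strata
#' (study A) or four (study B), a 1-h zero-order infusion of 7.5 (A) or 10
#' (B) mg/kg, two-compartment disposition with total absolute clearance
#' linear in Cockcroft-Gault creatinine clearance, a renal clearance fraction
#' proportional to renal function, multiplicative lognormal assay error, and
#' assay quantification limits of 0.25 (A) and 0.1 (B) ug/mL. Study B doses
#' are delivered at 90 percent of nominal (residual solution left in the
#' infusion line). Hydroxypropylbetadex, the solubilising excipient, is
#' carried as a second analyte with one-compartment, purely renal
#' disposition and ten times the telavancin mg/kg dose.
#'
#' @param study `"A"` or `"B"`.
#' @param n_per_stratum Named integer vector of subjects per stratum;
#'   defaults to the enrolment of the chosen study.
#' @param dose_mg_kg Nominal telavancin dose (7.5 or 10 mg/kg).
#' @param delivered_fraction Fraction of nominal dose actually delivered.
#' @param t_inf Infusion duration, h.
#' @param v1,v2,q Central/peripheral volumes (mL/kg) and inter-compartmental
#'   clearance (mL/h/kg) of the telavancin disposition model.
#' @param cl_intercept,cl_slope Absolute-clearance law CL(mL/h) =
#'   intercept + slope * CL_cr(mL/min).
#' @param fe0,clcr_ref Renal fraction fe = fe0 * CL_cr / clcr_ref, capped to
#'   [0, 1].
#' @param sigma Lognormal assay-error SD (log scale).
#' @param llq Plasma lower limit of quantification, ug/mL.
#' @param clcr_bands Named list of (lo, hi) target CL_cr ranges per stratum,
#'   mL/min, sampled uniformly when generating subjects.
#' @param hd_start,hd_duration,hd_qd,hd_cl Haemodialysis session start
#'   (h post-dose), duration (h), dialysate flow (mL/min) and true dialysis
#'   clearance (mL/h) for ESRD subjects.
#' @param hpb_v,hpb_cl_intercept,hpb_cl_slope,hpb_dose_ratio,hpb_llq
#'   Hydroxypropylbetadex one-compartment volume (mL/kg), clearance law
#'   (mL/h/kg vs CL_cr mL/min), dose multiple of the telavancin dose and LLQ.
#' @param seed Integer RNG seed; all stochastic output is a pure function of
#'   the configuration including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(study = c("A", "B"),
                       n_per_stratum = NULL,
                       dose_mg_kg = NULL,
                       delivered_fraction = NULL,
                       t_inf = 1,
                       v1 = 90, v2 = 55, q = 50,
                       cl_intercept = 315, cl_slope = 8.2,
                       fe0 = 0.8, clcr_ref = 100,
                       sigma = 0.10,
                       llq = NULL,
                       clcr_bands = NULL,
                       hd_start = 3, hd_duration = 4, hd_qd = 800, hd_cl = 270,
                       hpb_v = 270, hpb_cl_intercept = 2, hpb_cl_slope = 0.97,
                       hpb_dose_ratio = 10, hpb_llq = 10,
                       seed = 1L) {
  study <- match.arg(study)
  if (is.null(n_per_stratum))
    n_per_stratum <- if (study == "A")
      c(normal = 6L, mild = 7L, moderate = 6L, severe = 4L, esrd = 6L)
    else
      c(normal = 14L, mild = 13L, moderate = 8L, severe = 8L)
  if (is.null(dose_mg_kg)) dose_mg_kg <- if (study == "A") 7.5 else 10
  if (!dose_mg_kg %in% c(7.5, 10))
    stop("invalid input: dose must be 7.5 or 10 mg/kg")
  if (is.null(delivered_fraction)) delivered_fraction <- if (study == "A") 1 else 0.9
  if (is.null(llq)) llq <- if (study == "A") 0.25 else 0.1
  if (is.null(clcr_bands))
    clcr_bands <- list(normal = c(81, 120), mild = c(51, 80),
                       moderate = c(30, 50), severe = c(12, 29),
                       esrd = c(5, 15))
  if (study == "B" && "esrd" %in% names(n_per_stratum) && n_per_stratum[["esrd"]] > 0)
    stop("configuration error: ESRD is not a study-B stratum")
  stopifnot(v1 > 0, v2 > 0, q >= 0, fe0 >= 0, fe0 <= 1, sigma >= 0, llq > 0)
  structure(list(study = study, n_per_stratum = n_per_stratum,
                 dose_mg_kg = dose_mg_kg, delivered_fraction = delivered_fraction,
                 t_inf = t_inf, v1 = v1, v2 = v2, q = q,
                 cl_intercept = cl_intercept, cl_slope = cl_slope,
                 fe0 = fe0, clcr_ref = clcr_ref, sigma = sigma, llq = llq,
                 clcr_bands = clcr_bands,
                 hd_start = hd_start, hd_duration = hd_duration,
                 hd_qd = hd_qd, hd_cl = hd_cl,
                 hpb_v = hpb_v, hpb_cl_intercept = hpb_cl_intercept,
                 hpb_cl_slope = hpb_cl_slope, hpb_dose_ratio = hpb_dose_ratio,
                 hpb_llq = hpb_llq, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic subject cohort
#'
#' Draws demographics per stratum and back-solves each subject's serum
#' creatinine from a target creatinine clearance sampled uniformly within
#' the stratum's band, so that the Cockcroft-Gault value of every generated
#' subject lies inside its band by construction. Identical configurations
#' (including seed) give bit-identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @param .set_seed Internal; set `FALSE` when the caller manages the RNG.
#' @return Subjects data frame (`id, study, group, age_y, sex, race_black,
#'   weight_kg, height_cm, scr_mg_dl`) plus the generating `clcr_true`.
#' @export
generate_cohort <- function(config, .set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (.set_seed) set.seed(config$seed)
  rows <- list()
  for (stratum in names(config$n_per_stratum)) {
    n <- config$n_per_stratum[[stratum]]
    if (n == 0) next
    band <- config$clcr_bands[[stratum]]
    for (j in seq_len(n)) {
      clcr <- stats::runif(1, band[1], band[2])
      age <- round(stats::runif(1, 35, 75))
      sex <- if (stats::runif(1) < 0.5) "male" else "female"
      weight <- round(min(max(stats::rnorm(1, 75, 12), 50), 110), 1)
      height <- round(min(max(stats::rnorm(1, 170, 8), 150), 195))
      f <- if (sex == "female") 0.85 else 1
      scr <- (140 - age) * weight * f / (72 * clcr)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s-%s-%02d", config$study, toupper(substr(stratum, 1, 2)), j),
        study = config$study, group = stratum, age_y = age, sex = sex,
        race_black = 0L, weight_kg = weight, height_cm = height,
        scr_mg_dl = scr, clcr_true = clcr, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = character(), study = character(), group = character(),
                      age_y = numeric(), sex = character(), race_black = integer(),
                      weight_kg = numeric(), height_cm = numeric(),
                      scr_mg_dl = numeric(), clcr_true = numeric()))
  do.call(rbind, rows)
}

#' Apply multiplicative assay error and quantification-limit censoring
#'
#' Observed concentration = true concentration times `exp(N(0, sigma))`.
#' Any observed value below the LLQ (or a true zero) is flagged BLQ and its
#' concentration withheld (`NA`), mirroring how a bioanalytical report
#' presents below-limit samples.
#'
#' @param conc True concentrations, ug/mL.
#' @param sigma Lognormal SD (log scale); 0 means no noise.
#' @param llq Lower limit of quantification, ug/mL.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Data frame with `conc_ug_ml` (NA when BLQ) and `blq` (0/1).
#' @export
apply_assay_error <- function(conc, sigma, llq, seed = NULL) {
  if (sigma < 0) stop("invalid input: sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  obs <- if (sigma > 0) conc * exp(stats::rnorm(length(conc), 0, sigma)) else conc
  blq <- obs < llq
  data.frame(conc_ug_ml = ifelse(blq, NA_real_, obs), blq = as.integer(blq))
}

#' Simulate interval urine collections
#'
#' The amount excreted unchanged in each interval is the renal fraction of
#' clearance times the exact plasma AUC over that interval,
#' `fe * CL * AUC(t1, t2)`, scaled by body weight to milligrams; interval
#' urine volumes are drawn lognormally around a urine output rate and the
#' urine concentration is amount/volume. Over a full collection the analytic
#' total equals `fe * dose`.
#'
#' @param params [disposition_from_physiology()] parameters (must carry `fe`).
#' @param dose_per_kg Delivered dose, mg/kg.
#' @param weight Body weight, kg.
#' @param intervals Data frame with `start_h`, `end_h`; contiguity is not
#'   required but overlap is an error.
#' @param t_inf Infusion duration, h.
#' @param urine_rate_ml_h Median urine output rate for volume draws, mL/h.
#' @param volume_cv Lognormal SD of the volume draw (0 = fixed volumes).
#' @return `intervals` with `volume_ml`, `conc_ug_ml` and `amount_mg` added.
#' @export
simulate_urine <- function(params, dose_per_kg, weight, intervals,
                           t_inf = 1, urine_rate_ml_h = 60, volume_cv = 0.3) {
  stopifnot(inherits(params, "disposition_params"))
  ord <- order(intervals$start_h)
  intervals <- intervals[ord, , drop = FALSE]
  if (any(intervals$end_h <= intervals$start_h))
    stop("invalid input: interval end must exceed start")
  if (nrow(intervals) > 1 &&
      any(intervals$start_h[-1] < intervals$end_h[-nrow(intervals)] - 1e-9))
    stop("invalid input: overlapping urine intervals")
  auc <- mapply(function(a, b) analytic_auc(params, dose_per_kg, t_inf, a, b),
                intervals$start_h, intervals$end_h)
  amount_mg <- params$fe * params$cl * auc * weight / 1000
  dur <- intervals$end_h - intervals$start_h
  rate <- urine_rate_ml_h * exp(stats::rnorm(nrow(intervals), 0, volume_cv))
  volume <- dur * rate
  intervals$volume_ml <- volume
  intervals$conc_ug_ml <- amount_mg * 1000 / volume
  intervals$amount_mg <- amount_mg
  intervals
}

#' Simulate an intradialytic sampling session
#'
#' During a haemodialysis session the drug is removed from arterial plasma
#' at rate `cl_hd_true * C(t)`; each 30-min dialysate aliquot therefore
#' carries the exact integral of that rate over its interval, diluted into a
#' dialysate volume of `q_d` x 30 min. Arterial plasma samples are taken at
#' 0, 1, 2, 3 and 4 h after the session start. The plasma profile is the
#' subject's own disposition curve; intradialytic acceleration of the plasma
#' decline is not fed back (dialysis clearance is small relative to total
#' clearance and the session short).
#'
#' @param params,dose_per_kg,weight,t_inf As in [simulate_urine()].
#' @param session_start Session start, h after the start of infusion.
#' @param duration Session duration, h.
#' @param q_d Dialysate flow rate, mL/min.
#' @param cl_hd_true True dialysis clearance, mL/h.
#' @return List with `arterial` (time_h, conc_ug_ml), `dialysate`
#'   (start_min, end_min, conc_ug_ml, volume_ml) and `removed_mg`.
#' @export
simulate_dialysis <- function(params, dose_per_kg, weight, session_start,
                              duration = 4, q_d = 800, cl_hd_true = 270,
                              t_inf = 1) {
  stopifnot(inherits(params, "disposition_params"))
  if (session_start < 0 || duration <= 0 || cl_hd_true < 0 || q_d <= 0)
    stop("invalid input: session_start >= 0, duration > 0, q_d > 0, cl_hd_true >= 0")
  art_times <- session_start + seq(0, duration, by = 1)
  arterial <- data.frame(
    time_h = art_times,
    conc_ug_ml = simulate_concentrations(params, dose_per_kg, t_inf, art_times))
  bounds <- seq(0, duration, by = 0.5)
  start_h <- session_start + bounds[-length(bounds)]
  end_h <- session_start + bounds[-1]
  auc <- mapply(function(a, b) analytic_auc(params, dose_per_kg, t_inf, a, b),
                start_h, end_h)
  amount_ug <- cl_hd_true * auc              # mL/h * ug.h/mL
  volume_ml <- q_d * 30                      # mL per 30-min aliquot
  dialysate <- data.frame(
    start_min = (start_h - session_start) * 60 + session_start * 60,
    end_min = (end_h - session_start) * 60 + session_start * 60,
    conc_ug_ml = amount_ug / volume_ml,
    volume_ml = volume_ml)
  list(arterial = arterial, dialysate = dialysate,
       removed_mg = sum(amount_ug) / 1000)
}

#' Simulate a complete virtual study
#'
#' Generates the cohort, derives each subject's disposition from the
#' clearance-vs-creatinine-clearance law, simulates noiseless and observed
#' (noisy, LLQ-censored) plasma profiles for telavancin and
#' hydroxypropylbetadex, interval urine collections (study B), and a
#' haemodialysis session for each ESRD subject (study A). Everything is a
#' pure function of the configuration.
#'
#' @param config A [sim_config()] object.
#' @return List with data frames `subjects`, `truth` (per subject/analyte
#'   generating parameters), `concentrations` (observed, CSV schema),
#'   `concentrations_true` (noiseless), `urine`, `dialysate`, `dialysis_truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subjects <- generate_cohort(config, .set_seed = FALSE)
  conc <- conc_true <- urine <- dial <- truth <- dial_truth <- list()
  dose <- config$dose_mg_kg * config$delivered_fraction
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    cl_abs <- config$cl_intercept + config$cl_slope * s$clcr_true   # mL/h
    cl_kg <- cl_abs / s$weight_kg
    fe <- min(1, config$fe0 * s$clcr_true / config$clcr_ref)
    par_tlv <- disposition_from_physiology(cl_kg, config$v1, config$q, config$v2, fe)
    cl_hpb <- config$hpb_cl_intercept + config$hpb_cl_slope * s$clcr_true  # mL/h/kg
    par_hpb <- disposition_from_physiology(cl_hpb, config$hpb_v, 0, 0, fe = 1)
    times <- sampling_schedule(config$study, s$group)
    for (analyte in c("telavancin", "hydroxypropylbetadex")) {
      par <- if (analyte == "telavancin") par_tlv else par_hpb
      d <- if (analyte == "telavancin") dose else dose * config$hpb_dose_ratio
      llq <- if (analyte == "telavancin") config$llq else config$hpb_llq
      ct <- simulate_concentrations(par, d, config$t_inf, times)
      obs <- apply_assay_error(ct, config$sigma, llq)
      conc[[length(conc) + 1L]] <- data.frame(
        subject_id = s$id, analyte = analyte, time_h = times,
        conc_ug_ml = obs$conc_ug_ml, blq = obs$blq, stringsAsFactors = FALSE)
      conc_true[[length(conc_true) + 1L]] <- data.frame(
        subject_id = s$id, analyte = analyte, time_h = times,
        conc_ug_ml = ct, blq = 0L, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = s$id, analyte = analyte, stratum = s$group,
        clcr_true = s$clcr_true, weight_kg = s$weight_kg,
        dose_mg_kg = d, dose_mg = d * s$weight_kg,
        cl_ml_h_kg = par$cl, vss_ml_kg = par$vss, fe = par$fe,
        lambda_z_true = min(par$lambda),
        auc_inf_true = d * 1000 / par$cl, stringsAsFactors = FALSE)
      if (config$study == "B" && analyte %in% c("telavancin", "hydroxypropylbetadex")) {
        u <- simulate_urine(par, d, s$weight_kg, urine_intervals(),
                            t_inf = config$t_inf)
        urine[[length(urine) + 1L]] <- data.frame(
          subject_id = s$id, analyte = analyte,
          start_h = u$start_h, end_h = u$end_h, volume_ml = u$volume_ml,
          conc_ug_ml = u$conc_ug_ml, blq = 0L, stringsAsFactors = FALSE)
      }
    }
    if (config$study == "A" && s$group == "esrd") {
      d <- simulate_dialysis(par_tlv, dose, s$weight_kg, config$hd_start,
                             config$hd_duration, config$hd_qd, config$hd_cl,
                             t_inf = config$t_inf)
      dial[[length(dial) + 1L]] <- cbind(subject_id = s$id, d$dialysate,
                                         stringsAsFactors = FALSE)
      dial_truth[[length(dial_truth) + 1L]] <- data.frame(
        subject_id = s$id, removed_mg = d$removed_mg,
        dose_mg = dose * s$weight_kg, cl_hd_true = config$hd_cl,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(subjects = subjects, truth = bind(truth),
       concentrations = bind(conc), concentrations_true = bind(conc_true),
       urine = bind(urine), dialysate = bind(dial),
       dialysis_truth = bind(dial_truth))
}
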