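#' @name study_io
#' @title Delimited-text schemas for study data
#' @description
#' All study inputs and outputs are plain CSV. Schemas (column order fixed):
#' \itemize{
#'   \item subjects: `id, study, group, age_y, sex, race_black, weight_kg,
#'     height_cm, scr_mg_dl`
#'   \item concentrations: `subject_id, analyte, time_h, conc_ug_ml, blq`
#'   \item urine: `subject_id, analyte, start_h, end_h, volume_ml,
#'     conc_ug_ml, blq`
#'   \item dialysate: `subject_id, start_min, end_min, conc_ug_ml, volume_ml`
#' }
#' Times are hours after the start of infusion. BLQ rows carry `NA`
#' concentration. Reading then writing any table round-trips to full stored
#' precision.
NULL

.check_schema <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", what, " file '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read a long-format concentration table
#'
#' Validates the schema, sorts each subject/analyte profile by time, blanks
#' BLQ concentrations, and rejects duplicate (subject, analyte, time)
#' records.
#'
#' @param path CSV file path.
#' @return Data frame in the concentrations schema.
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("subject_id", "analyte", "time_h", "conc_ug_ml", "blq"),
                "concentration", path)
  if (!nrow(df)) {
    warning("empty concentration file: ", path)
    return(df)
  }
  key <- paste(df$subject_id, df$analyte, df$time_h)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop("duplicate record: subject ", d$subject_id, " analyte ", d$analyte,
         " time ", d$time_h, " h appears more than once")
  }
  df$conc_ug_ml[df$blq == 1] <- NA_real_
  df[order(df$subject_id, df$analyte, df$time_h), , drop = FALSE]
}

#' @rdname read_concentrations
#' @param df Table to write.
#' @export
write_concentrations <- function(df, path) {
  utils::write.csv(df[c("subject_id", "analyte", "time_h", "conc_ug_ml", "blq")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write the subjects table
#' @param path CSV file path.
#' @return Data frame in the subjects schema.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("id", "study", "group", "age_y", "sex", "race_black",
                      "weight_kg", "height_cm", "scr_mg_dl"), "subjects", path)
  df
}

#' @rdname read_subjects
#' @param df Table to write.
#' @export
write_subjects <- function(df, path) {
  cols <- c("id", "study", "group", "age_y", "sex", "race_black",
            "weight_kg", "height_cm", "scr_mg_dl")
  utils::write.csv(df[intersect(c(cols, "clcr_true"), names(df))], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write the urine-interval table
#' @param path CSV file path.
#' @return Data frame in the urine schema.
#' @export
read_urine <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("subject_id", "analyte", "start_h", "end_h",
                      "volume_ml", "conc_ug_ml", "blq"), "urine", path)
  df
}

#' @rdname read_urine
#' @param df Table to write.
#' @export
write_urine <- function(df, path) {
  utils::write.csv(df[c("subject_id", "analyte", "start_h", "end_h",
                        "volume_ml", "conc_ug_ml", "blq")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write the dialysate-aliquot table
#' @param path CSV file path.
#' @return Data frame in the dialysate schema.
#' @export
read_dialysate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("subject_id", "start_min", "end_min", "conc_ug_ml",
                      "volume_ml"), "dialysate", path)
  df
}

#' @rdname read_dialysate
#' @param df Table to write.
#' @export
write_dialysate <- function(df, path) {
  utils::write.csv(df[c("subject_id", "start_min", "end_min", "conc_ug_ml",
                        "volume_ml")], path, row.names = FALSE)
  invisible(path)
}

#' Published group-level reference values
#'
#' The group summary statistics (mean, SD, n) published for the two
#' single-dose telavancin renal-impairment phase-1 studies: plasma
#' non-compartmental parameters by stratum, urinary mass-balance parameters
#' (study B), protein binding and dialysis clearance (study A), and the
#' normal-group mean body weight. These printed values serve as desk-check
#' inputs for the exposure-comparison arithmetic; subject-level study data
#' were never published.
#'
#' @return Data frame `study, stratum, analyte, parameter, units, n, mean, sd`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "reference_group_means.csv", package = "renalpk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Chains simulate, NCA, urinary mass balance (study B), dialysis clearance
#' (study A ESRD), stratum summaries with outlier annotation, exposure
#' comparisons and the clearance-vs-creatinine-clearance regression, writing
#' every table as CSV plus a run log. Deterministic given the configuration.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) a list with all computed tables: `sim`, `nca`,
#'   `summary`, `comparisons`, `cl_reduction`, `regression`, and where
#'   applicable `urine_results`, `dialysis`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  say("pipeline start: study ", config$study, ", seed ", config$seed,
      ", dose ", config$dose_mg_kg, " mg/kg x ", config$delivered_fraction)

  sim <- simulate_study(config)
  write_subjects(sim$subjects, file.path(out_dir, "subjects.csv"))
  write_concentrations(sim$concentrations, file.path(out_dir, "concentrations.csv"))
  say("simulated ", nrow(sim$subjects), " subjects")

  nca <- run_nca_table(sim$concentrations, sim$truth, t_inf = config$t_inf)
  utils::write.csv(nca, file.path(out_dir, "nca_results.csv"), row.names = FALSE)
  say("NCA complete: ", nrow(nca), " profiles")

  params <- c("cmax", "t_half", "auc_0_inf", "cl", "vss")
  tlv <- nca[nca$analyte == "telavancin", ]
  summ <- summarize_by_stratum(tlv, params)
  summ$mean_sd <- sprintf("%.1f ± %.1f", summ$mean, summ$sd)
  utils::write.csv(summ, file.path(out_dir, "summary_by_stratum.csv"),
                   row.names = FALSE)
  fl <- summ[nzchar(summ$outlier_ids), ]
  for (i in seq_len(nrow(fl)))
    say("outlier flagged (retained): ", fl$parameter[i], " in ", fl$stratum[i],
        ": ", fl$outlier_ids[i])

  auc_means <- tapply(tlv$auc_0_inf, tlv$stratum, mean)
  strata_order <- intersect(c("normal", "mild", "moderate", "severe", "esrd"),
                            names(auc_means))
  comp <- red <- NULL
  if ("normal" %in% strata_order && length(strata_order) > 1) {
    comp <- percent_increase_vs_normal(auc_means[strata_order])
    utils::write.csv(comp, file.path(out_dir, "exposure_comparisons.csv"),
                     row.names = FALSE)
    cl_means <- tapply(tlv$cl, tlv$stratum, mean)
    red <- percent_reduction_vs_normal(cl_means[strata_order])
    utils::write.csv(red, file.path(out_dir, "cl_reduction.csv"), row.names = FALSE)
  } else {
    say("exposure comparisons skipped: no normal reference stratum")
  }

  subj <- sim$subjects
  clcr <- subj$clcr_true[match(tlv$subject_id, subj$id)]
  reg <- cl_vs_clcr_regression(clcr, tlv$cl * tlv$weight_kg)
  say(sprintf("CL vs CLcr regression: slope %.2f, intercept %.1f, r2 %.3f (n=%d)",
              reg$slope, reg$intercept, reg$r_squared, reg$n))

  out <- list(sim = sim, nca = nca, summary = summ, comparisons = comp,
              cl_reduction = red, regression = reg)

  if (!is.null(sim$urine)) {
    ur <- urine_results(sim$urine, nca, sim$concentrations, sim$truth,
                        target_dose_mg_kg = config$dose_mg_kg)
    utils::write.csv(ur, file.path(out_dir, "urine_results.csv"), row.names = FALSE)
    say("urine mass balance: ", nrow(ur), " profiles")
    out$urine_results <- ur
  }
  if (!is.null(sim$dialysate)) {
    rows <- list()
    for (sid in unique(sim$dialysate$subject_id)) {
      d <- sim$dialysate[sim$dialysate$subject_id == sid, ]
      tr <- sim$dialysis_truth[sim$dialysis_truth$subject_id == sid, ]
      co <- sim$concentrations_true[sim$concentrations_true$subject_id == sid &
                                      sim$concentrations_true$analyte == "telavancin", ]
      mid <- (d$start_min + d$end_min) / 2 / 60
      par_c <- stats::approx(co$time_h, co$conc_ug_ml, xout = mid, rule = 2)$y
      clhd_rec <- mean(dialysis_clearance(config$hd_qd, par_c, d$conc_ug_ml,
                                          variant = "recovery"))
      clhd_pr <- mean(dialysis_clearance(config$hd_qd, par_c, d$conc_ug_ml,
                                         variant = "as_printed"))
      removed <- dialysate_cumulative(d$conc_ug_ml, d$volume_ml)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, cl_hd_recovery_ml_min = clhd_rec,
        cl_hd_as_printed_ml_min = clhd_pr, removed_mg = removed,
        pct_dose_removed = fraction_removed(removed, tr$dose_mg),
        stringsAsFactors = FALSE)
    }
    dial <- do.call(rbind, rows)
    utils::write.csv(dial, file.path(out_dir, "dialysis_results.csv"),
                     row.names = FALSE)
    say(sprintf("dialysis: mean CL_HD (recovery) %.2f mL/min, mean %% removed %.1f",
                mean(dial$cl_hd_recovery_ml_min), mean(dial$pct_dose_removed)))
    out$dialysis <- dial
  }

  say("pipeline complete")
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out)
}
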