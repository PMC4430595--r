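#' Creatinine clearance by the Cockcroft-Gault equation
#'
#' Estimates creatinine clearance from age, actual body weight, serum
#' creatinine and sex:
#' \deqn{CL_{cr} = \frac{(140 - age) \times weight}{72 \times S_{cr}}
#'   \times 0.85 \; (\mathrm{if\ female})}
#'
#' This is the renal-function surrogate used to stratify study-A subjects and
#' to relate total body clearance to renal function in both studies.
#'
#' @param age Age in years; must be positive and below 140.
#' @param weight Actual body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param sex `"male"` or `"female"`.
#' @return Creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")   # 100 mL/min
#' cockcroft_gault(40, 72, 1.0, "female") # 85 mL/min
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(scr <= 0) || any(weight <= 0))
    stop("invalid input: weight and serum creatinine must be positive")
  if (any(age <= 0) || any(age >= 140))
    stop("invalid input: age must be in (0, 140) years")
  clcr <- (140 - age) * weight / (72 * scr)
  if (sex == "female") clcr <- clcr * 0.85
  clcr
}

#' Estimated GFR by the 4-variable MDRD equation
#'
#' \deqn{eGFR = k \times S_{cr}^{-1.154} \times age^{-0.203}
#'   \times 0.742 \;(\mathrm{female}) \times 1.212 \;(\mathrm{black})}
#'
#' The coefficient `k` defaults to 186, appropriate for creatinine assays that
#' are not IDMS-traceable (the alkaline-picrate UV assays of the study era);
#' use 175 for IDMS-standardised assays.
#'
#' @param age Age in years (> 0).
#' @param scr Serum creatinine in mg/dL (> 0).
#' @param sex `"male"` or `"female"`.
#' @param race_black Logical; black race indicator of the 4-variable equation.
#' @param coefficient Leading constant, 186 (default) or 175.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
mdrd_egfr <- function(age, scr, sex, race_black = FALSE, coefficient = 186) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(age <= 0) || any(scr <= 0))
    stop("invalid input: age and serum creatinine must be positive")
  egfr <- coefficient * scr^-1.154 * age^-0.203
  if (sex == "female") egfr <- egfr * 0.742
  if (isTRUE(race_black)) egfr <- egfr * 1.212
  egfr
}

#' Body surface area (DuBois-DuBois)
#'
#' \deqn{BSA = 0.007184 \times H^{0.725} \times W^{0.425}}
#'
#' Used to express Cockcroft-Gault clearance per 1.73 m^2 when comparing with
#' eGFR-based stratification.
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @return Body surface area in m^2.
#' @export
body_surface_area <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0))
    stop("invalid input: height and weight must be positive")
  0.007184 * height^0.725 * weight^0.425
}

#' Assign a renal-impairment stratum
#'
#' Classifies a renal-function value into the five strata used in the two
#' studies. Study A stratifies on Cockcroft-Gault creatinine clearance
#' (mL/min): normal > 80, mild (50, 80], moderate [30, 50], severe < 30, with
#' subjects maintained on dialysis assigned to ESRD regardless of the value.
#' Study B stratifies on MDRD eGFR (mL/min/1.73 m^2): normal >= 90, mild
#' [60, 90), moderate [30, 60), severe [15, 30); ESRD is not a study-B
#' category and values below 15 are unclassifiable under that scheme.
#'
#' The printed study-A bands are integer ranges ("51-80", "30-50"); the
#' half-open continuous bands above cover the whole non-negative axis with no
#' gap or overlap while agreeing with the printed bands at every integer.
#'
#' @param value Renal-function value (CL_cr mL/min for `study_A_clcr`, eGFR
#'   mL/min/1.73 m^2 for `study_B_egfr`). Must be non-negative.
#' @param scheme `"study_A_clcr"` or `"study_B_egfr"`.
#' @param on_dialysis Logical; maintained on haemodialysis (study A only).
#' @return One of `"normal"`, `"mild"`, `"moderate"`, `"severe"`, `"esrd"`.
#' @export
classify_renal_function <- function(value, scheme = c("study_A_clcr", "study_B_egfr"),
                                    on_dialysis = FALSE) {
  scheme <- match.arg(scheme)
  if (length(value) != 1L || is.na(value) || value < 0)
    stop("invalid input: renal-function value must be a single non-negative number")
  if (isTRUE(on_dialysis)) {
    if (scheme == "study_B_egfr")
      stop("unsupported category: ESRD is not a study-B stratum")
    return("esrd")
  }
  if (scheme == "study_A_clcr") {
    if (value > 80) "normal"
    else if (value > 50) "mild"
    else if (value >= 30) "moderate"
    else "severe"
  } else {
    if (value >= 90) "normal"
    else if (value >= 60) "mild"
    else if (value >= 30) "moderate"
    else if (value >= 15) "severe"
    else stop("unsupported category: eGFR < 15 is unclassifiable under the study-B scheme")
  }
}

#' Renal-function assessment for a subject table
#'
#' Computes Cockcroft-Gault clearance (absolute and BSA-normalised), MDRD
#' eGFR, and the renal stratum for every subject. Subjects in the ESRD group
#' (study A `group == "esrd"`) are treated as maintained on dialysis.
#'
#' @param subjects Data frame with columns `id, study, group, age_y, sex,
#'   race_black, weight_kg, height_cm, scr_mg_dl` (the subjects CSV schema).
#' @param mdrd_coefficient Passed to [mdrd_egfr()].
#' @return The input with columns `clcr_cg` (mL/min), `clcr_cg_bsa`
#'   (mL/min/1.73 m^2), `egfr_mdrd` (mL/min/1.73 m^2) and `stratum` appended.
#' @export
assess_renal_function <- function(subjects, mdrd_coefficient = 186) {
  stopifnot(is.data.frame(subjects))
  n <- nrow(subjects)
  clcr <- egfr <- bsa <- numeric(n)
  stratum <- character(n)
  for (i in seq_len(n)) {
    s <- subjects[i, ]
    clcr[i] <- cockcroft_gault(s$age_y, s$weight_kg, s$scr_mg_dl, s$sex)
    egfr[i] <- mdrd_egfr(s$age_y, s$scr_mg_dl, s$sex, isTRUE(s$race_black == 1 | s$race_black == TRUE),
                         coefficient = mdrd_coefficient)
    bsa[i] <- body_surface_area(s$height_cm, s$weight_kg)
    on_hd <- !is.null(s$group) && identical(as.character(s$group), "esrd")
    stratum[i] <- if (s$study == "A")
      classify_renal_function(clcr[i], "study_A_clcr", on_dialysis = on_hd)
    else
      classify_renal_function(egfr[i], "study_B_egfr")
  }
  subjects$clcr_cg <- clcr
  subjects$clcr_cg_bsa <- clcr * 1.73 / bsa
  subjects$egfr_mdrd <- egfr
  subjects$stratum <- stratum
  subjects
}
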