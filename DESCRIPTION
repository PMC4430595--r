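Package: renalpk
Title: Non-Compartmental Pharmacokinetics of Telavancin Across Renal Function Strata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the pharmacokinetic analysis of single-dose telavancin
    phase-1 studies in subjects with varying degrees of renal impairment:
    renal-function estimation and stratification (Cockcroft-Gault, MDRD),
    non-compartmental analysis of plasma concentration-time profiles
    (terminal slope, AUC, clearance, volume at steady state), urinary
    mass-balance and renal clearance, haemodialysis clearance and dialysate
    recovery, plasma protein binding, and cohort-level exposure comparisons.
    A seeded virtual-cohort simulator generates bi-exponential infusion
    profiles, urine collections and dialysis sessions with assay error and
    limit-of-quantification censoring, so the full pipeline runs and is
    testable without access to subject-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
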