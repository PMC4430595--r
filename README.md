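# renalpk

Pharmacokinetic analysis of single-dose telavancin in subjects with varying
degrees of renal impairment, for clinical pharmacologists and
pharmacometricians who need the full chain from raw concentration–time,
urine and dialysate tables to stratum-level exposure comparisons — plus a
seeded virtual-cohort simulator so the whole pipeline runs and is testable
without access to subject-level study data.

Telavancin is a lipoglycopeptide antibiotic cleared mainly by the kidney,
so exposure (AUC) rises and clearance falls as renal function declines. The
package implements the analysis of the two phase-1 renal-impairment studies
of telavancin (study A, 7.5 mg/kg, five strata including haemodialysed ESRD
subjects; study B, 10 mg/kg, four strata with 96-h urine collection):

* **Renal stratification** — Cockcroft–Gault
  `CLcr = (140 − age)·W / (72·Scr)` (×0.85 female), 4-variable MDRD eGFR,
  DuBois body surface area, and the two studies' classification bands.
* **Non-compartmental analysis** — Cmax/tmax, automatic terminal-slope
  (λz) window selection by maximal adjusted r², linear and
  lin-up/log-down trapezoidal AUC, `AUC0–∞ = AUC0–t + Clast/λz`, AUMC and
  `MRT = AUMC/AUC0–∞ − tinf/2`, `CL = dose/AUC0–∞`, `Vss = CL·MRT`, with
  the study's BLQ policy (only measurable concentrations used).
* **Mass balance** — urinary `Ae`, `Ae% = Ae/dose·100`, renal clearance
  `CLR = Ae/AUC` over matched intervals, dose normalisation; haemodialysis
  clearance in both published forms (`QD(C−D)/C` as printed, and the
  dialysate-recovery form `QD·D/C`), cumulative dialysate recovery;
  equilibrium-dialysis protein binding `%bound = (donor−receptor)/donor·100`.
* **Cohort statistics** — mean ± SD summaries, Tukey-fence outlier
  annotation (flagged, never excluded), percent AUC increase / CL reduction
  versus the normal-function group, and OLS regression of absolute CL
  (mL/h) on CLcr (mL/min).
* **Simulation** — two-compartment closed-form infusion profiles with
  CL linear in CLcr, lognormal assay error, LLQ censoring, urine intervals
  and a 4-h dialysis session for ESRD; everything a pure function of a
  `sim_config()` including its seed.

## Worked example

```r
library(renalpk)
cfg <- sim_config("A", seed = 42)      # 29-subject study-A design, 7.5 mg/kg
out <- run_pipeline(cfg, tempdir())
out$comparisons
#>    stratum ratio_vs_normal pct_increase pct_rounded
#> 1     mild           1.336        33.58          34
#> 2 moderate           1.750        75.00          75
#> 3   severe           2.209       120.93         121
#> 4     esrd           2.952       195.17         195
as.data.frame(out$regression)
#>   slope intercept r_squared  n
#> 1 7.993     312.2    0.9881 29
```

Exposure in this simulated cohort roughly doubles in severe impairment
relative to normal renal function (+121 % in mean AUC0–∞), and absolute
clearance tracks creatinine clearance almost linearly (r² = 0.99, slope
≈ 8 mL/h per mL/min) — the qualitative picture the real studies report.
The per-stratum summary shows mean clearance falling from 14.9 ± 2.7
(normal) to 6.8 ± 1.5 mL/h/kg (severe) while half-life rises from
6.9 ± 1.0 to 15.6 ± 3.8 h; one ESRD half-life is Tukey-flagged in the run
log and retained. `out$dialysis` reports both haemodialysis-clearance
variants and the percent of dose removed per simulated ESRD subject.

The published group-level summaries of the two studies ship as a
plain-text table, `reference_group_means()`, for desk checks such as
reproducing the reported exposure-increase integers from the printed mean
AUCs.

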