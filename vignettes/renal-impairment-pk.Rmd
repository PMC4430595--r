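---
title: "Methods: renal-impairment pharmacokinetics of telavancin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: renal-impairment pharmacokinetics of telavancin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalpk)
```

## Scope and scientific setting

Telavancin is a lipoglycopeptide antibiotic eliminated largely unchanged in
urine, so its exposure rises as kidney function falls. `renalpk` implements
the complete analysis of two single-dose phase-1 renal-impairment studies of
telavancin and its solubilising excipient hydroxypropylbetadex: study A
(7.5 mg/kg, five strata including ESRD subjects dialysed on the dosing day)
and study B (10 mg/kg, four strata, with 96-h urine collections). Because no
subject-level data from those studies are public, the package pairs the
analysis code with a seeded virtual-cohort simulator, and keeps the
published group-level summary statistics as a plain-text reference table
(`reference_group_means()`) for desk checks of the exposure-comparison
arithmetic.

## Renal-function stratification

Study A stratifies on Cockcroft–Gault creatinine clearance,
$CL_{cr} = (140-\mathrm{age})\,W / (72\,S_{cr})$, times 0.85 for women;
study B on the 4-variable MDRD eGFR,
$186\,S_{cr}^{-1.154}\mathrm{age}^{-0.203}(0.742\ \mathrm{if\ female})
(1.212\ \mathrm{if\ black})$. Choices made where the study description is
silent:

* The published study-A bands are integer ranges (">80", "51–80", "30–50",
  "<30"), which leave values such as 50.5 undefined on a continuous scale.
  We use half-open continuous bands — normal $>80$, mild $(50, 80]$,
  moderate $[30, 50]$, severe $<30$ — which agree with the printed bands at
  every integer and tile $[0,\infty)$ with no gap or overlap. Study B uses
  $\ge 90$, $[60,90)$, $[30,60)$, $[15,30)$; below 15 is unclassifiable
  there because ESRD was not a study-B category, and the classifier raises
  an error rather than guessing.
* Subjects maintained on dialysis are ESRD regardless of their computed
  clearance (study A scheme only).
* The MDRD leading coefficient defaults to 186: the studies' creatinine
  assays were alkaline-picrate UV methods, which predate IDMS
  standardisation. It is an argument (`coefficient = 175` for IDMS assays),
  not a hard-coded constant.
* Cockcroft–Gault uses actual body weight; the body-surface-area
  normalisation (for comparing with eGFR units) uses the DuBois–DuBois
  formula $0.007184\,H^{0.725}W^{0.425}$, the usual pharmacometric default.

## Disposition model and simulator

Plasma telavancin declines bi-exponentially after the 1-h zero-order
infusion, so the simulator uses a two-compartment model parameterised by
(CL, V1, Q, V2), converted to macro constants in closed form: the exponents
are the roots of $\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda +
k_{10}k_{21} = 0$. Concentrations, interval AUCs and the total area
$AUC_{0-\infty} = \mathrm{dose}/CL$ are all analytic, which lets the urine
and dialysis simulators satisfy mass balance exactly and gives the tests an
exact oracle.

Defaults (all in `sim_config()`, none hard-coded) emulate the study
population:

* **Clearance law.** Absolute clearance is linear in creatinine clearance,
  $CL\,(\mathrm{mL/h}) = 315 + 8.2\,CL_{cr}\,(\mathrm{mL/min})$. The two
  constants were fixed by passing a line through the points implied by the
  published stratum means (normal: 13.7 mL/h/kg at 79 kg and
  $CL_{cr}\approx94$; severe: 6.18 mL/h/kg at 80 kg and
  $CL_{cr}\approx22$). With these, simulated stratum-mean clearances and
  half-lives fall inside the published mean ± SD bands
  (normal ≈ 14 mL/h/kg and 7 h; severe ≈ 6–7 mL/h/kg and 15 h).
* **Volumes.** $V_1 = 90$, $V_2 = 55$ mL/kg, so $V_{ss} = 145$ mL/kg, inside
  the published 131–157 mL/kg range; $Q = 50$ mL/h/kg reproduces a distinct
  distribution phase with a terminal half-life near 7.7 h at normal
  function.
* **Renal fraction.** $f_e = f_{e0} \cdot CL_{cr}/CL_{cr,\mathrm{ref}}$
  capped to $[0,1]$, with $f_{e0} = 0.8$ at the reference 100 mL/min —
  healthy subjects excrete roughly 82 % of a dose unchanged, and the renal
  share shrinks with renal function in favour of metabolic elimination.
  Simulated normal-function urinary recovery (~80 % of dose) is therefore
  higher than the published study-B normal-group value (~63 %); the
  simulator reproduces the monotone decline across strata, not that
  absolute level.
* **Subjects.** Each subject's target $CL_{cr}$ is drawn uniformly inside
  its stratum band and the serum creatinine back-solved through
  Cockcroft–Gault, so generated subjects are in-band by construction.
  Demographics (age 35–75, weight N(75, 12) truncated, height N(170, 8))
  are plausible for the enrolled population; the studies publish only group
  means, not distributions, so these are free simulator choices.
* **Error model.** Multiplicative lognormal assay error (default CV ≈ 10 %,
  a free parameter — the studies report no variance components), because
  concentrations span two orders of magnitude and must stay positive.
  Observed values below the LLQ (0.25 µg/mL study A, 0.1 µg/mL study B) are
  flagged BLQ and their concentrations withheld.
* **Delivered dose.** Study B delivered about 10 % less than nominal
  (residual solution in the infusion line): `delivered_fraction = 0.9`.
* **Hydroxypropylbetadex.** Second analyte, one-compartment
  (V = 270 mL/kg), purely renal clearance $2 + 0.97\,CL_{cr}$ mL/h/kg
  (half-life ≈ 2 h at normal function, strongly prolonged in ESRD), dosed
  at ten times the telavancin mg/kg dose (the formulation contains 100 mg
  of excipient per 10 mg of drug).

What the simulator deliberately omits: inter-occasion variability,
covariate effects beyond renal function, protein-binding kinetics (binding
is a static fraction), and the feedback of the dialysis session on the
plasma curve (dialysis clearance is small relative to total clearance and
the session short, so aliquot amounts are computed from the undisturbed
curve). Passing tests therefore demonstrate correctness of the estimators
on data satisfying the model's assumptions — they cannot certify behaviour
on real profiles with model misspecification.

## Non-compartmental analysis

`run_nca()` computes the standard single-dose parameter set. Decisions on
points the study reports leave open:

* **Terminal slope.** The λz window is chosen automatically: every window
  of ≥ 3 quantifiable points ending at the last quantifiable sample and
  starting strictly after the peak is fitted log-linearly; the largest
  adjusted $r^2$ wins, ties going to the longer window. This mirrors the
  best-fit automation of the commercial NCA software used in the studies,
  whose exact settings were not reported; agreement with the published
  results is therefore distributional, not per-subject.
* **AUC method.** Linear trapezoid by default (the era's common default);
  `lin_up_log_down` applies the logarithmic trapezoid on strictly declining
  positive panels and falls back to linear on rising, flat or zero-bounded
  panels (no division by $\ln 1$).
* **BLQ policy.** Pre-dose BLQ samples become 0 and anchor the curve;
  embedded and trailing BLQ samples are excluded, so only measurable
  concentrations enter the calculations.
* **Extrapolation.** $AUC_{0-\infty} = AUC_{0-t} + C_{last}/\lambda_z$ with
  the *observed* last quantifiable concentration; AUMC adds the analytic
  tail $C_{last}(t_{last}/\lambda_z + 1/\lambda_z^2)$ (linear trapezoid on
  $t\cdot C$ under either AUC method, standard moment-analysis practice);
  $MRT = AUMC/AUC_{0-\infty} - t_{inf}/2$ corrects the zero-order input,
  and $V_{ss} = CL \cdot MRT$.
* **ESRD clearance.** Reported as the subject's total clearance including
  any dialysis contribution — no correction is applied at the NCA stage,
  matching how the study tabulated it.

On noiseless simulated cohorts sampled on the actual study-B schedule these
choices recover the generating clearance within 2 %, half-life within 2 %
and $V_{ss}$ within 5 % (the acceptance tests assert exactly this).

## Excretion, dialysis and binding

Urinary mass balance follows the study's printed formulas: interval amount
= concentration × volume; $Ae\% = Ae/\mathrm{dose} \times 100$;
$CL_R = Ae/AUC$ with amount and area over the *same* interval (the matched
span is enforced by comparing interval bounds exactly, and runs to the last
quantifiable plasma sample within the urine span). The extrapolation
$Ae_{0-\infty} = Ae_{0-t} + CL_R \cdot W \cdot AUC_{tail}/1000$ is our
choice — the study does not state its method — and is consistent both with
the study's own $CL_R$ definition and with the near-identical published
$Ae_{0-t}$/$Ae_{0-\infty}$ pairs. Amounts can be dose-normalised to the
nominal 10 mg/kg dose, which leaves all percentages invariant.

Haemodialysis clearance is deliberately implemented twice. The study's
printed formula $CL_{HD} = Q_D(C_{TLV}-D_{TLV})/C_{TLV}$ evaluates to
nearly the dialysate flow itself (~795 mL/min) for any realistic
concentration pair, which cannot be reconciled with the reported clearance
of 4.5 mL/min; the dialysate-recovery form $Q_D D_{TLV}/C_{TLV}$ reproduces
that magnitude exactly. Both variants are exposed
(`dialysis_clearance(..., variant =)`), the printed formula is the default
out of fidelity to the source, and the pipeline reports both. Cumulative
dialysate recovery multiplies each 30-min aliquot concentration by the
aliquot dialysate volume ($Q_D \times 30$ min = 24 L at 800 mL/min) and
sums.

Protein binding uses the equilibrium-dialysis formulas
$\%bound = (donor-receptor)/donor \times 100$; the unbound percentage is
computed as $100 - \%bound$ so the pair sums to 100 exactly in floating
point.

## Cohort statistics

Group summaries are arithmetic mean ± sample SD, the form of the published
tables; exposure comparisons are ratios of arithmetic stratum means
(`100(\bar{AUC}_g/\bar{AUC}_{normal} - 1)`, rounded to integers only for
display). Outlier screening uses Tukey fences with Tukey's hinges
(median-split halves, the `fivenum` convention — the study does not name
its quartile convention, and the shipped examples are stable across
conventions); flagged values are annotated and always retained, as in the
source analyses. The clearance–renal-function relationship is ordinary
least squares of absolute clearance (mL/h) on un-normalised
Cockcroft–Gault clearance (mL/min), with $r^2$ the squared Pearson
correlation.

The published per-stratum means ± SD and the study $r^2$ values (0.76 and
0.62) depend on subject-level data that were never released, so they are
not asserted numerically anywhere; instead the tests check the qualitative
structure — stratum-mean AUC strictly increasing and clearance strictly
decreasing with impairment, and $r^2 \to 1$ in the noiseless limit.

## Numerical and degenerate-input conventions

All times are hours after the start of infusion. Peak ties resolve to the
earliest time. A profile whose concentrations rise to the last observation
raises a no-terminal-decline error; fewer than three post-peak points, an
insufficient-data error; an all-BLQ profile, a no-data error — the
table-level driver converts per-profile failures into warnings naming the
subject and analyte and continues. Tukey screening below n = 4 warns and
flags nothing. Zero doses, zero AUCs, non-positive donor concentrations and
overlapping urine intervals are rejected with `invalid input` errors rather
than propagating NaN.

## Problem sizes

The shipped tests simulate cohorts of 11–16 subjects per study arm and use
dense grids of 400–2000 points for the closed-form oracles; the acceptance
script runs the two full study designs (29 and 43 subjects) once each plus
one noiseless replicate. These sizes were chosen as the smallest at which
every property is comfortably away from its tolerance.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config("A", seed = 42)
out <- run_pipeline(cfg, tempdir())
out$comparisons      # per-stratum AUC ratios vs normal
out$regression       # CL (mL/h) vs CLcr (mL/min)
```
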