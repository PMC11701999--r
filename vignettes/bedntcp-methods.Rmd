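---
title: "BED-based NTCP modeling of late rectal bleeding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BED-based NTCP modeling of late rectal bleeding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedntcp)
```

## The modeling problem

Moderately hypofractionated prostate radiotherapy (e.g. 19 fractions of
3.4 Gy) delivers a different biological dose to the rectum than
conventional fractionation (39 fractions of 2 Gy) even where the physical
dose is the same.  To pool two such trial arms into a single dose-response
model for grade ≥2 late rectal bleeding (G2 LRB), `bedntcp` converts each
patient's rectal dose distribution voxelwise to the biologically effective
dose (BED) of the linear-quadratic model,

$$\mathrm{BED}(D) = D\left(1 + \frac{D/N}{\alpha/\beta}\right),$$

where $D$ is the voxel's total physical dose, $N$ the number of fractions
(so $D/N$ is the voxel's dose per fraction), and $\alpha/\beta$ the tissue
sensitivity to fractionation (3 Gy is the conventional late-rectum
assumption, and the package default).  Because the conversion is strictly
monotone in $D$ for fixed $N$ and $\alpha/\beta$, applying it to the bin
doses of a differential dose-volume histogram (DVH) is exactly equivalent
to converting voxel doses and re-histogramming; the package therefore
operates on DVHs throughout.

A useful analytic consequence: two prescriptions deliver the same
prescription BED at the crossover
$\alpha/\beta = (D_a d_a - D_b d_b)/(D_b - D_a)$.  For 78 Gy/39 fx vs
64.6 Gy/19 fx this is 4.7 Gy — below it the hypofractionated arm has the
higher BED, which is why the fractionation-sensitivity assumption is the
pivotal input of the whole analysis.

## Dosimetric predictors

Three families of DVH summaries serve as candidate dose predictors, all
computed on the BED axis:

* **gEUD** $\;(\sum_i v_i D_i^{1/n})^n$ with relative volumes $v_i$; the
  volume exponent $n \in (0, 1]$ interpolates between mean dose ($n = 1$)
  and maximum dose ($n \to 0$).  Small $n$ (0.05–0.2) encodes the serial
  organ behavior expected for rectal bleeding.  Evaluated in log space so
  exponents as small as $10^{-3}$ are stable.
* **$V_D$** — relative volume (%) receiving at least $D$ Gy BED.  The
  differential-bin convention treats each bin's volume as mass at its
  representative dose; a bin counts when its dose is at or above the
  threshold.  Because thresholds of interest are quoted at one decimal
  (V111.9 is "the BED of physical 70 Gy under 39 × 2 Gy at
  $\alpha/\beta$ = 3", whose exact value is 111.88 Gy), the comparison
  allows a 0.05 Gy tolerance — half the printed precision.  This is a
  presentation-precision accommodation, not smoothing; it is configurable
  (`tol`).
* **$D_{x\mathrm{cm}^3}$** — minimum dose in the hottest $x$ cm³, found by
  linear interpolation on the cumulative absolute-volume curve.  With the
  generator's 0.5 Gy bins the interpolation error is below half a bin.

## Endpoint and eligibility

G2 LRB is scored from two sources combined by logical OR: any bleeding
medication/intervention on the case report form, or patient-reported
bleeding that is "moderate" on at least two distinct questionnaires or
"severe" on at least one.  Events after clinical recurrence are ignored,
and bleeding adjudicated as caused by severe hemorrhoids is never an
event (adjudication is an input flag; it cannot be automated).  We read
"two moderate questionnaires" as two *distinct visits*.  Eligibility
requires ≥12 months follow-up, no recurrence before month 12, at least
one toxicity evaluation after month 12, and available planning data.

## Model development

For each candidate dose parameter a separate logistic model starts from
{dose metric, ABD_SURG, HYPOTREAT}, where ABD_SURG is prior abdominal
surgery and HYPOTREAT indicates the hypofractionated arm.  Development
has three stages:

1. **AIC backward elimination.**  The predictor whose removal most
   decreases AIC is dropped until no removal decreases it.  Equal-AIC ties
   drop the later-listed candidate, so the dose metric is maximally
   protected; the criterion is deterministic.  If HYPOTREAT survives, the
   dose parameter failed to capture the between-arm difference and the
   model is disqualified — this retention flag is the key qualitative
   output of the sensitivity analysis.
2. **Bootstrap uniform shrinkage** (default 300 resamples).  The full
   procedure — elimination included — is replayed on each resample; the
   resample model's linear predictor is evaluated on the original data
   and the calibration slope of the original outcomes on it is recorded.
   The shrinkage factor $s$ is the mean slope; replaying selection inside
   the bootstrap is the default (`reselect = TRUE`) because selection is
   part of the procedure being validated.  Degenerate resamples (single
   outcome class, non-convergence, intercept-only) are excluded and
   counted.
3. **Shrinkage + intercept re-estimation.**  Slopes are multiplied by $s$
   (final OR = OR$^s$), then the intercept is re-fit by ML with the
   shrunk linear predictor as offset, restoring mean predicted risk =
   observed prevalence.

IRLS runs with deviance tolerance $10^{-12}$ and at most 100 iterations;
separation is flagged when a standardized slope exceeds 20 in magnitude
and the fit is treated as non-converged rather than an error, so
bootstrap loops can skip it.

## Internal validation

Apparent and optimism-corrected performance follow Harrell's bootstrap:
per resample, the full procedure is re-run, performance is measured on
the resample and on the original data, and the difference is the
optimism; corrected = apparent − mean optimism, with percentile 95%
intervals of (apparent − optimism$_b$).  Measures: rank-based AUC
(midrank ties), Brier score, calibration slope and intercept (logistic
recalibration on the logit of predictions, the intercept with the logit
as offset), and the integrated calibration index (ICI) — the mean
absolute gap between a loess calibration curve and the identity.  The
loess smoother is degree-1 with tricube weights; the span is not a
published quantity, so we use 0.75, the common default for calibration
curves, configurable and recorded in the report.  The ICI and its
interval are clipped at 0.  Whether shrinkage is re-estimated inside each
optimism resample is likewise unstated in the literature this follows; the
default replays it (inner bootstrap of 100) via `ntcp_procedure()`, and
`nested_shrinkage = FALSE` gives the cheaper selection-only variant used
in most of the test suite.

Note one bookkeeping choice: `optimism_correct()` measures apparent
performance with whatever procedure it is given.  When that procedure
includes shrinkage, the apparent calibration slope is slightly above 1 by
construction (shrinkage deliberately flattens predictions); the classical
"apparent slope = 1.00" identity holds for the unshrunk ML model, which
is how the acceptance tests assert it.

## The synthetic cohort generator

No patient-level data from the source trial are public, so the generator
is a first-class module with a known ground truth rather than a test
fixture.  It emulates a two-arm randomized cohort: arm ~ Bernoulli(0.5)
(CF 78 Gy/39 fx vs HF 64.6 Gy/19 fx), prior abdominal surgery ~
Bernoulli(0.20), and outcome drawn from
$\mathrm{logit}\,p = \beta_0 + \beta_\mathrm{dose}\,\mathrm{EUD}_{n=0.1}^{\mathrm{BED}} + \beta_\mathrm{abd}\,\mathrm{ABD}$
with $\beta_\mathrm{dose} = \ln 1.08$ per Gy BED and
$\beta_\mathrm{abd} = \ln 1.88$ — effect sizes of the magnitude reported
for this endpoint.  $\beta_0$ is calibrated by root-finding so the
expected prevalence is 14% (the observed 89/656).  Follow-up visits are
synthesized so that the endpoint scorer reproduces the drawn outcome
exactly, with ~87% of events encoded on the case report form and ~13% as
questionnaire-only patterns (mirroring 77 vs 12 of 89 events).

DVH shapes are invented, since none are published: total rectal volume is
log-normal (median 60 cm³, log-sd 0.3, a typical whole-rectum contour
range), and the cumulative relative-volume curve is flat to 30% of the
prescription then falls off logistically with a patient-specific midpoint
and width driven by a Beta(2, 4) "high-dose overlap" parameter, truncated
within 5% above prescription.  These choices produce realistic-looking
serial-organ DVHs and wide overlap of the arms' BED-EUD distributions,
but they do **not** reproduce real inter-patient anatomy, planning-margin
effects, or within-arm dose heterogeneity.  Consequently the synthetic
dose-response is cleaner than clinical data: discrimination is higher
(AUC ≈ 0.7 vs ≈ 0.65) and shrinkage factors are nearer 1 than the 0.88 to
0.93 seen in practice.  Passing tests demonstrate that the *pipeline* is
correct — BED arithmetic, selection, shrinkage, validation — not that the
generator reproduces clinical operating characteristics.

Presets (`scenario_presets()`): `hypro-like` (n = 656 as above), `null`
(zero slopes), `overfit` (n = 200, ~28 events for 3 candidates, below the
10 events-per-variable rule), and `low-alphabeta` (true
$\alpha/\beta$ = 1.5 Gy).  Identical preset and seed give byte-identical
cohort files.

Direction checks follow the BED arithmetic: for true $\alpha/\beta$ below
the 4.7 Gy crossover the HF arm receives the higher BED and shows the
higher bleeding incidence (as observed clinically, 18.2% vs 10.7%); above
the crossover the direction reverses.  Tests use $\alpha/\beta$ = 1.5 and
8 Gy for the two sides.

## Sensitivity analysis

`run_grid()` reruns the full pipeline over a grid of assumed
$\alpha/\beta$ values (default 2 and 3 Gy) and dose parameters (gEUD
$n \in \{0.05, 0.1, 0.15, 0.2\}$, $D_{0.1\mathrm{cm}^3}$,
$D_{2\mathrm{cm}^3}$, and $V_D$ thresholds recomputed per $\alpha/\beta$
as the BED equivalents of physical 70 and 75 Gy under the conventional
schedule — e.g. V147.1 at $\alpha/\beta$ = 2).  Each cell's seed is
derived deterministically from the grid seed and the cell spec, so
results are identical in any cell order and each cell is reproducible in
isolation.  Cell failures are recorded and the grid continues.
"HYPOTREAT retained" after AIC elimination is the disqualification
criterion; Wald p-values are reported for information only.

## Problem sizes and numerical choices

Defaults are chosen for faithful methodology at interactive scale:
shrinkage B = 300 and optimism B = 1000 mirror standard practice; the
test suite and examples use smaller cohorts (200–5000 patients) and
bootstrap sizes (15–200), which are ample to verify the arithmetic
identities, oracle equivalences, and Monte-Carlo properties they target.
Simulation-based checks fix their seeds; coefficient-recovery assertions
use 3 standard errors, and null-optimism assertions use 2 Monte-Carlo
standard errors.

One property is inherently marginal and worth stating plainly: when the
assumed $\alpha/\beta$ equals the generator's truth, HYPOTREAT is a truly
null predictor given the dose metric, and AIC retains a null predictor
whenever its likelihood-ratio statistic exceeds 2 — probability
$P(\chi^2_1 > 2) \approx 0.157$.  The expected elimination rate is
therefore ≈84%, and any 20-seed batch fluctuates around it (standard
deviation ≈8 percentage points).  This is a property of AIC selection
itself, not of the implementation; the abstract logistic simulation in
the test suite reproduces the 15.7% retention rate exactly.

## Known limitations

* No DICOM handling: DVHs enter as CSV exports; contouring and dose-grid
  effects are upstream of this package.
* BED only; no overall-treatment-time term (the two schedules' time
  difference is assumed irrelevant for late rectal toxicity).
* The generator's DVH shapes and covariate structure are invented
  defaults; absolute performance numbers on synthetic cohorts should not
  be read as clinical estimates.
* No time-to-event modeling: the endpoint is a fixed-horizon binary
  indicator with post-recurrence exclusion.
* LKB-style joint estimation of $\alpha/\beta$ with profile likelihood is
  out of scope; the sensitivity grid varies the assumption instead.
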