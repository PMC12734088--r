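---
title: "Threshold-anchored MMG metrics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-anchored MMG metrics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgstrat)
```

## The measurement problem

Intraoperative mechanomyography (MMG) probes a nerve root's excitability by
stimulating it directly and detecting the mechanical muscle twitch with a
skin-surface accelerometer. The recorded quantity is the stimulation
threshold: the lowest current, in milliamperes, that evokes a response.
Compressed nerve roots need more current; published work places normal nerve
function at thresholds of roughly 1–2 mA. A surgeon decompressing a root can
therefore measure the threshold before and after the decompression and ask
whether the nerve has physiologically recovered.

The naive summary — percentage change from baseline — treats a 15 → 10 mA
nerve (33% improvement, still far above normal) the same as a 3 → 2 mA nerve
(33% improvement, fully normalized). The package's central metrics instead
anchor everything to a fixed physiologic reference \(R\) (default
\(R = 2.0\) mA, the upper bound of the published normal range):

* **Threshold Reduction Ratio (TRR)**, per nerve with baseline elevation
  (\(pre > R\)):
  \[
    \mathrm{TRR} \;=\; \frac{(pre - R) - \max(post - R,\, 0)}{pre - R},
  \]
  the fraction of the baseline elevation eliminated by surgery (1 = complete
  normalization, 0 = no change). The patient-level TRR is the mean over the
  patient's elevated nerves.
* **Threshold Excess (TE)**, per patient:
  \(\mathrm{TE} = \max(\overline{post} - R,\, 0)\) mA — the residual
  pathology left on the table, clamped at zero.

Clinical outcome is the Numeric Pain Scale (NPS, integer 0–10) at baseline
and six weeks; the analysis outcome is the improvement fraction
\((\mathrm{NPS}_{pre} - \mathrm{NPS}_{6wk})/\mathrm{NPS}_{pre}\), undefined
at a zero baseline (such patients — operated for functional impairment
rather than pain — are excluded from all improvement analyses and reported
as exclusions). Binary outcomes are complete relief
(\(\mathrm{NPS}_{6wk}=0\)) and the minimal clinically important difference
(MCID: a ≥ 2-point drop OR ≥ 30% of baseline).

## Boundary conventions that matter

Several edge cases are underdetermined by the formulas above; the package
resolves them as follows.

* **TRR at exactly the reference.** A nerve with \(pre = R\) has baseline
  elevation 0, making TRR a 0/0. A nerve contributes to TRR only when
  \(pre > R\) strictly; patients with no such nerve have an undefined TRR
  and are excluded from TRR analyses (with their ids logged).
* **Worsening nerves.** TRR is not clamped below: a nerve whose threshold
  rose scores negative, preserving information. The study cohort contained
  no worsening nerve, so worsening is an advisory validation flag, not an
  error.
* **Percentage change.** No canonical formula exists for the patient level;
  the package computes the ratio-of-aggregates
  \((\overline{pre} - \overline{post})/\overline{pre}\) under the
  configured aggregation, and the nerve-level summary additionally reports
  the mean of per-nerve percentage reductions. The two differ (Jensen), so
  both are computed and labeled.
* **Aggregation.** Patients with several nerves are summarized by the mean
  (default), the *index* nerve (highest pre-decompression threshold) or the
  *worst* nerve (highest post-decompression threshold); ties break to the
  first nerve in input order, which is why nerve order is preserved at
  parse time. For single-nerve patients all three coincide (tested as an
  invariant).
* **Integrality.** The stimulation protocol moves in 1 mA increments, so
  thresholds are integers in practice; the data model stores decimals so
  externally collected datasets with averaged or fractional thresholds
  load, and non-integrality is a validation warning rather than an error.

## Inferential toolkit

All intervals are 95% with \(z = 1.959964\) held at full precision;
rounding happens only in display formatting.

* **Correlations** use the Fisher-z interval
  \(\tanh(\operatorname{atanh} r \pm z/\sqrt{n-3})\) and a t-based p-value
  on \(n-2\) df. This closed form reproduces printed intervals from an
  \((r, n)\) pair alone, which the acceptance script exploits.
* **Competing metrics** are compared with Steiger's z-test for dependent
  correlations sharing one variable (the averaged-correlation covariance
  form). The comparison is only meaningful on the *matched subset* —
  patients for whom both metrics are defined — so the pipeline computes
  both correlations and their inter-correlation on exactly that subset.
* **Dose–response**: OLS of the improvement fraction on TE (and a
  covariate-adjusted TRR model: baseline pain, nerve count, region), via
  `stats::lm` with t-based intervals; logistic regression of complete
  relief on TE via binomial IRLS (`stats::glm`, tolerance 1e-8, 100
  iterations max), reporting the per-mA odds ratio with both a Wald
  interval and a seeded percentile bootstrap over patient resamples
  (default 2000; the resample count is exposed because bootstrap
  conventions vary). A constant predictor is special-cased to the flat
  likelihood answer (OR = 1) rather than a collinearity failure.
* **2×2 tables** report the sample odds ratio \((ad)/(bc)\) with a
  two-sided exact p-value by hypergeometric mass summation (the
  Fisher-style convention). An uncorrected chi-square or a Yates-corrected
  test would give visibly different p-values on small tables, so the output
  labels the method. Zero cells trigger the Haldane–Anscombe 0.5
  correction, flagged.
* **Proportions** get Wilson score intervals, which behave sensibly at the
  small per-stratum counts (n = 8–17) this design produces.
* No multiple-comparison correction is applied anywhere: the analysis is
  explicitly hypothesis-generating, and the report exposes raw p-values.

## Cross-validation and shrinkage

Internal validity is assessed by leave-one-out cross-validation of each
metric → outcome linear model: for every patient the model is refitted
without them and their outcome predicted. The package computes per-fold
fits by downdating the regression's sufficient statistics, which is exactly
equivalent to refitting and makes LOOCV at n = 2000 immediate; stored
per-fold predictions and slopes let the tests recompute every summary by
brute force.

`cv_r` is the correlation between actual outcomes and held-out predictions,
and cross-validated \(R^2\) is defined as `cv_r`², matching the convention
that pairs a cross-validated correlation with its square. Shrinkage is the
percentage decrease from apparent to cross-validated performance. One
wrinkle: held-out predictions correlate *positively* with outcomes whenever
the model carries signal, regardless of the predictor's own sign, so for a
negatively correlated predictor (TE) the literal ratio
\((r_{app} - r_{cv})/r_{app}\) is meaningless. The package therefore uses
\((|r_{app}| - r_{cv})/|r_{app}|\), which is identical for
positively-correlated metrics and sensible for TE — whose cross-validated
story is anyway better told by its RMSE, squared cross-validated
correlation and per-fold slope stability, all of which are reported.

k-fold validation uses a seeded partition stratified by outcome
above/below the median (to reduce partition variance); with \(k = n\) it
reduces exactly to LOOCV. The fold assignment is recorded in the result.

## Stratified tables and cut-point screening

Outcome tables stratify patients by TRR (complete normalization = exactly
1; substantial 0.6–1; partial < 0.6) and by TE (< 0.5 mA; 0.5–2.5 mA;
≥ 2.5 mA), reporting per-stratum mean improvement with a Student-t interval
(n − 1 df) and the complete-relief rate with its Wilson interval. Stratum
specifications carry explicit boundary inclusivity so the point category
TRR = 1 coexists with half-open intervals; a value falling in no category
is an error, never silent loss.

Cut-point screening classifies a patient test-positive when the mean
post-decompression threshold is at or below a candidate cutoff and
tabulates sensitivity/specificity/PPV/NPV against an explicitly named
binary outcome — complete relief, MCID, or any improvement. The outcome
must be named because screening results are only interpretable relative to
a stated target; the full report emits all three scans. Candidate cutoffs
default to midpoints between sorted unique observed values plus the
reference, which exhausts the distinct confusion matrices; AUC comes from
the rank (Mann–Whitney) statistic with ties counted half, which equals the
trapezoidal area over an exhaustive scan (tested to 1e-9).

The related *sufficiency plateau* check asks, among patients who reached
the reference (TE = 0), whether pushing thresholds further down is
associated with further pain improvement — a near-zero correlation supports
treating the reference as "low enough".

## The synthetic cohort generator

The generator emulates the study conditions so that the entire pipeline is
testable without clinical data: 42 patients; 1–6 nerves each (categorical
distribution with mean 2.73); 76% lumbar; integer baseline thresholds
\(1 + \mathrm{round}(\Gamma(k, \theta))\) truncated to [1, 25] with
\(k = 1.757,\ \theta = 3.659\), calibrated once against the targeted
moments (nerve-level mean ≈ 7.4 mA, SD ≈ 4.9, ≈ 90% above 2 mA — a Gamma
family was chosen because only moments and tail fractions are specified;
the calibration, not the family, is what the Monte-Carlo tests assert).
Within-patient baselines share a Gaussian-copula exchangeable correlation
(default 0.3 — a plausibility choice; the within-patient correlation is
not reported anywhere, so it is flagged as unanchored). Recovery is a
mixture: an elevated nerve improves with probability 0.891; improvers
normalize to at or below the reference with probability 0.522, otherwise
the removed fraction of elevation is Beta(2, 2) and the residual is
rounded back to an integer strictly between the reference and the
baseline. No nerve ever worsens.

Baseline pain is zero with probability 0.05 (generated deliberately to
exercise the exclusion pathway) and otherwise a rounded
Normal(7.16, 1.9) clamped to 1–10, giving overall mean ≈ 6.8 and SD ≈ 2.4.
Outcome coupling is linear in TE on the improvement-fraction scale:
\(\mathrm{frac} = \mathrm{clip}(0.92 - 0.063\,\mathrm{TE} + \varepsilon,\,
0, 1)\), \(\varepsilon \sim N(0, 0.22)\), and the six-week NPS is
\(\mathrm{round}(\mathrm{NPS}_{pre}(1-\mathrm{frac}))\) — pain scores stay
integers end-to-end, so observed improvement fractions take the rational
values a real NPS produces.

Clipping at the [0, 1] boundary attenuates the recoverable slope slightly
(the fitted mean slope across replicates sits near −0.055 against the
nominal −0.063), which is why the parameter-recovery tolerance is ±0.01
rather than exact, and why CI coverage runs a little below nominal. Under
a null coupling (slope 0) the clip is outcome-independent of TE, and the
slope test's empirical size is correct (checked at 200 replicates).

**What passing tests do and do not show.** The generator reproduces the
marginal structure (threshold distributions, improvement/normalization
rates, pain moments) and a linear TE–outcome coupling with Gaussian noise.
It does not model chronicity, age or comorbidity effects on achievable
thresholds, procedure-specific differences, informative follow-up loss, or
any nonlinearity in the dose–response. Green tests therefore demonstrate
that the *pipeline* is correct and internally stable under the assumed
data-generating process — not that the clinical findings generalize.

## Problem sizes and determinism

Simulation-backed tests use: 200 pooled seeds for generator calibration,
200 replicates for slope recovery and for the null size check, 100 cohorts
for the shrinkage inequality, one n = 2000 cohort for the large-n
shrinkage limit, and 1500 trivariate-normal draws for the Steiger size
check — sizes chosen to keep Monte-Carlo error comfortably inside each
asserted tolerance. Every stochastic component (generator, bootstrap,
k-fold partition) takes an explicit seed and restores the caller's RNG
state; LOOCV is deterministic by construction, and rerunning the full
report with an identical configuration reproduces every output file
byte-for-byte.

## Worked example

```{r}
coh <- generate_cohort(synthetic_config(), seed = 1)
coh
rep <- run_full_analysis(coh, bootstrap_reps = 200, seed = 17)
rep$correlations$te
rep$crossval$trr
format_strata(stratify(rep$metrics, te_default_strata()))
```

## Known limitations

* The percentage-change metric's patient-level definition is a convention
  (ratio of aggregates); other choices would shift its correlation
  slightly.
* The exact-test convention for 2×2 tables (mass summation) is one of
  several defensible two-sided definitions; the report labels it.
* The generator's within-patient correlation and the Beta shape of partial
  recovery are plausibility choices, not estimates.
* Cut-point screening is hypothesis-generating: no corrected intervals for
  data-driven cutoffs are produced, by design.
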