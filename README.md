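# mmgstrat

Threshold-anchored mechanomyography (MMG) metrics for quantifying spinal
nerve-root decompression and relating it to early pain outcomes.

## The problem

During lumbar or cervical decompression surgery, MMG measures a nerve
root's stimulation threshold — the lowest current (mA) that evokes a
mechanical muscle response — before and after the root is decompressed.
Thresholds at or below about 2.0 mA represent normal nerve function;
compressed roots need more current. The question for the surgeon is whether
the decompression moved the nerve back into the normal range, and the
question for the analyst is how to quantify that movement so it predicts
how the patient will feel at six weeks.

Percentage change from baseline is the conventional answer, but it ignores
where the nerve ends up: 15 → 10 mA and 3 → 2 mA are both "33% better",
yet only the second nerve has normalized. `mmgstrat` implements two metrics
anchored to a physiologic reference threshold *R* (default 2.0 mA):

* **Threshold Reduction Ratio** — per nerve with baseline elevation
  (*pre* > *R*):

  TRR = ((pre − R) − max(post − R, 0)) / (pre − R)

  the fraction of baseline elevation eliminated (1 = complete
  normalization); patient-level TRR is the mean over elevated nerves.

* **Threshold Excess** — per patient:

  TE = max(mean(post) − R, 0)   (mA)

  the residual pathology remaining above the reference.

Around these metrics the package provides the full analysis pipeline:
CSV ingest with strict validation, pain outcomes (improvement fraction,
MCID, complete relief), three nerve-to-patient aggregation strategies,
Pearson correlations with Fisher-z intervals, Steiger's test for comparing
dependent correlations, linear and logistic dose–response models with
bootstrap intervals, exact 2×2 odds ratios, Wilson score intervals,
stratified outcome tables, cut-point screening, leave-one-out and k-fold
cross-validation with shrinkage, and a seeded synthetic-cohort generator
that emulates the study conditions (42 patients, ~112 nerves, right-skewed
elevated baselines, no threshold worsening, linear TE–outcome coupling)
for end-to-end testing and parameter-recovery experiments.

## Worked example

```r
library(mmgstrat)

coh <- generate_cohort(synthetic_config(), seed = 1)
coh
#> MMG decompression cohort: 42 patients, 119 nerves
#>   regions: cervical 13, lumbar 29

m <- compute_metrics(coh)
head(m[, c("patient_id", "mean_pre_mA", "mean_post_mA", "trr", "te",
           "pain_improvement_frac")], 3)
#>   patient_id mean_pre_mA mean_post_mA       trr  te pain_improvement_frac
#> 1       S001        11.0          8.5 0.2777778 6.5             0.5000000
#> 2       S002         3.5          2.0 1.0000000 0.0             1.0000000
#> 3       S003        12.0          9.0 0.3000000 7.0             0.1666667

rep <- run_full_analysis(coh, bootstrap_reps = 200, seed = 17)
rep$correlations$te
#> r = -0.720 (95% CI -0.842 to -0.526), n = 40, p = 1.678e-07
rep$crossval$trr
#> LOOCV cross-validation of trr, n = 38
#>   apparent r = 0.454, cv r = 0.313, shrinkage = 31.0%
#>   apparent R^2 = 0.206, cv R^2 = 0.098 (loss 52.4%)
#>   RMSE = 0.227, mean per-fold slope = 0.4529
```

Reading: in this simulated cohort, each mA of residual Threshold Excess is
associated with less pain improvement (r = −0.72 across the 40 patients
with baseline pain; the TE dose–response slope in
`rep$dose_response` is −0.074, i.e. about 7.4 percentage points less
improvement per mA), and the TRR → outcome model retains a cross-validated
correlation of 0.31 after leave-one-out refitting. `run_full_analysis()`
also returns stratified TRR/TE outcome tables with Wilson intervals, the
matched-subset Steiger comparison of TRR against percentage change, the
at-reference 2×2 odds ratio, cut-point scans for three outcomes, and the
exclusion log; with `out_dir =` it writes `metrics.csv`, `analysis.json`,
`crossval.json`, `strata.csv`, `cutpoints.csv` and a text summary.

Real data load from two CSVs via
`read_cohort("nerves.csv", "patients.csv")` — columns
`patient_id, nerve_label, pre_mA, post_mA` and
`patient_id, region, nps_pre, nps_6wk`.

## Documentation

The methods vignette (`vignettes/threshold-anchored-mmg.Rmd`) documents the
models and their assumptions, every boundary convention (TRR at the
reference, worsening nerves, aggregation tie-breaks), the cross-validation
and shrinkage definitions, the generator's calibration and its limits, and
the numerical design choices.
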