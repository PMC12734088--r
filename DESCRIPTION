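Package: mmgstrat
Title: Threshold-Anchored Mechanomyography Metrics for Spinal Decompression Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes threshold-anchored metrics of intraoperative
    mechanomyography (MMG) stimulation thresholds recorded before and after
    spinal nerve-root decompression, and relates them to early pain outcomes.
    Implements the Threshold Reduction Ratio (TRR, the fraction of a nerve's
    baseline threshold elevation above a physiologic 2.0 mA reference that is
    eliminated by decompression) and the Threshold Excess (TE, the residual
    patient-level post-decompression threshold above the reference), alongside
    conventional percentage change, with three nerve-to-patient aggregation
    strategies. Provides the accompanying inferential toolkit (Pearson
    correlations with Fisher-z intervals, Steiger's test for dependent
    correlations, linear and logistic dose-response models with bootstrap
    intervals, exact 2x2 odds ratios, Wilson score intervals), leave-one-out
    and k-fold cross-validation with shrinkage, stratified outcome tables,
    cut-point screening, and a seeded synthetic-cohort generator for
    end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
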