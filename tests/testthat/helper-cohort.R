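# Small in-code fixtures shared across test files.

# one-call cohort builder: nerves as a list of per-patient (pre, post) matrices
make_cohort <- function(nerves, nps_pre, nps_6wk,
                        region = rep("lumbar", length(nerves))) {
  ids <- sprintf("P%d", seq_along(nerves))
  pts <- data.frame(patient_id = ids, region = region,
                    nps_pre = nps_pre, nps_6wk = nps_6wk,
                    stringsAsFactors = FALSE)
  nrv <- do.call(rbind, lapply(seq_along(nerves), function(i) {
    m <- nerves[[i]]
    data.frame(patient_id = ids[i],
               nerve_label = sprintf("N%d", seq_len(nrow(m))),
               pre_mA = m[, 1], post_mA = m[, 2],
               stringsAsFactors = FALSE)
  }))
  as_cohort(pts, nrv)
}

# the single concordant non-improvement patient: three unchanged elevated
# nerves (9->9, 6->6, 5->5) and unchanged pain (NPS 6 at both timepoints)
unchanged_patient_cohort <- function() {
  make_cohort(list(cbind(c(9, 6, 5), c(9, 6, 5))), nps_pre = 6, nps_6wk = 6)
}

# metrics-shaped table built directly, for stratification/cut-point tests
fake_metrics <- function(mean_post, improvement, relief,
                         trr = NULL, te = NULL, mcid = NULL) {
  n <- length(mean_post)
  data.frame(patient_id = sprintf("F%d", seq_len(n)),
             region = "lumbar", n_nerves = 1L,
             mean_pre_mA = mean_post + 5, mean_post_mA = mean_post,
             pct_change = 0.5,
             trr = if (is.null(trr)) 0.5 else trr,
             te = if (is.null(te)) pmax(mean_post - 2, 0) else te,
             nps_pre = 8L, nps_6wk = 2L,
             pain_improvement_frac = improvement,
             mcid = if (is.null(mcid)) improvement >= 0.3 else mcid,
             complete_relief = relief,
             aggregation_used = "mean",
             stringsAsFactors = FALSE)
}
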