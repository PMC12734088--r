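#' Threshold Reduction Ratio for a single nerve
#'
#' The TRR measures what fraction of a nerve's baseline threshold elevation
#' above the physiologic reference (default 2.0 mA) was eliminated by
#' decompression:
#' \deqn{TRR = \frac{(pre - R) - \max(post - R, 0)}{pre - R}}
#' A value of 1 is complete normalization (post at or below the reference);
#' 0 is no change. The ratio is undefined (`NA`) when the nerve had no
#' baseline elevation (`pre_mA <= reference_mA`), since there is nothing to
#' reduce; strict inequality avoids a 0/0 at exactly the reference. A nerve
#' that worsened (post > pre) yields a negative TRR rather than a clamped
#' value, preserving the information; the cohort-level expectation that no
#' nerve worsens is enforced only as a [validate_cohort()] warning.
#'
#' @param pre_mA,post_mA stimulation thresholds (mA), vectorized.
#' @param reference_mA physiologic reference threshold, default 2.0 mA.
#' @return numeric vector; `NA` where undefined. Always `<= 1`.
#' @export
#' @examples
#' nerve_trr(9, 9)    # unchanged elevated nerve: 0
#' nerve_trr(8, 2)    # complete normalization: 1
#' nerve_trr(10, 6)   # (8 - 4) / 8 = 0.5
#' nerve_trr(2, 1)    # no baseline elevation: NA
nerve_trr <- function(pre_mA, post_mA, reference_mA = 2.0) {
  stopifnot(all(pre_mA >= 0), all(post_mA >= 0))
  elev_pre <- pre_mA - reference_mA
  elev_post <- pmax(post_mA - reference_mA, 0)
  out <- (elev_pre - elev_post) / elev_pre
  out[elev_pre <= 0] <- NA_real_
  out
}

#' Patient-level Threshold Reduction Ratio
#'
#' Mean of [nerve_trr()] across the patient's nerves that had baseline
#' elevation (`pre_mA > reference_mA`); `NA` when no nerve qualifies.
#'
#' @inheritParams nerve_trr
#' @return length-1 numeric, `NA` if undefined.
#' @export
patient_trr <- function(pre_mA, post_mA, reference_mA = 2.0) {
  stopifnot(length(pre_mA) >= 1L, length(pre_mA) == length(post_mA))
  r <- nerve_trr(pre_mA, post_mA, reference_mA)
  if (all(is.na(r))) return(NA_real_)
  mean(r, na.rm = TRUE)
}

#' Select a patient's summarizing nerve
#'
#' `"index"` picks the nerve with the highest pre-decompression threshold,
#' `"worst"` the highest post-decompression threshold. Ties are broken by
#' first occurrence in the stored (read) order.
#'
#' @inheritParams nerve_trr
#' @param strategy `"index"` or `"worst"`.
#' @return integer position of the selected nerve.
#' @export
select_nerve <- function(pre_mA, post_mA, strategy = c("index", "worst")) {
  strategy <- match.arg(strategy)
  stopifnot(length(pre_mA) >= 1L, length(pre_mA) == length(post_mA))
  if (strategy == "index") which.max(pre_mA) else which.max(post_mA)
}

#' Patient-level Threshold Excess
#'
#' TE is the residual post-decompression threshold above the reference,
#' clamped at zero: `max(agg_post - reference, 0)` where `agg_post` is the
#' mean post-decompression threshold (mean aggregation) or the selected
#' nerve's post threshold (index/worst aggregation). TE = 0 means the patient
#' reached normal-range thresholds; each additional mA is residual pathology.
#'
#' @inheritParams nerve_trr
#' @param aggregation `"mean"`, `"index"` or `"worst"`.
#' @return length-1 non-negative numeric (mA).
#' @export
#' @examples
#' patient_te(c(9, 6, 5), c(9, 6, 5))   # mean post 6.67 -> TE 4.67
patient_te <- function(pre_mA, post_mA, reference_mA = 2.0,
                       aggregation = c("mean", "index", "worst")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(pre_mA) >= 1L, length(pre_mA) == length(post_mA))
  agg_post <- if (aggregation == "mean") {
    mean(post_mA)
  } else {
    post_mA[select_nerve(pre_mA, post_mA, aggregation)]
  }
  max(agg_post - reference_mA, 0)
}

#' Patient-level percentage threshold change
#'
#' Conventional relative improvement `(agg_pre - agg_post) / agg_pre` under
#' the chosen aggregation, as a fraction of baseline (1 = thresholds fell to
#' zero). Unlike TRR and TE this metric is not anchored to the physiologic
#' reference: a 15 to 10 mA change and a 3 to 2 mA change both score 1/3.
#'
#' @inheritParams patient_te
#' @return length-1 numeric fraction; `NA` if the aggregated pre is zero.
#' @export
patient_pct_change <- function(pre_mA, post_mA,
                               aggregation = c("mean", "index", "worst")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(pre_mA) >= 1L, length(pre_mA) == length(post_mA))
  if (aggregation == "mean") {
    agg_pre <- mean(pre_mA); agg_post <- mean(post_mA)
  } else {
    i <- select_nerve(pre_mA, post_mA, aggregation)
    agg_pre <- pre_mA[i]; agg_post <- post_mA[i]
  }
  if (agg_pre <= 0) return(NA_real_)
  (agg_pre - agg_post) / agg_pre
}

#' Pain outcome quantities for one patient
#'
#' From baseline and six-week Numeric Pain Scale scores derives:
#' \describe{
#'   \item{improvement_frac}{`(nps_pre - nps_6wk) / nps_pre`; `NA` when the
#'     baseline is 0 (undefined; such patients are excluded from all
#'     improvement-fraction analyses).}
#'   \item{mcid}{minimal clinically important difference: reduction of at
#'     least `mcid_points` points OR at least `mcid_fraction` of baseline.}
#'   \item{complete_relief}{six-week NPS of exactly 0.}
#' }
#'
#' @param nps_pre,nps_6wk NPS scores, integers in 0--10 (vectorized).
#' @param config a [metric_config()].
#' @return data.frame with columns `improvement_frac`, `mcid`,
#'   `complete_relief`.
#' @export
#' @examples
#' pain_outcomes(c(6, 8, 3), c(6, 0, 2))
pain_outcomes <- function(nps_pre, nps_6wk, config = metric_config()) {
  stopifnot(all(nps_pre >= 0 & nps_pre <= 10),
            all(nps_6wk >= 0 & nps_6wk <= 10))
  frac <- ifelse(nps_pre > 0, (nps_pre - nps_6wk) / nps_pre, NA_real_)
  mcid <- (nps_pre - nps_6wk >= config$mcid_points) |
    (nps_pre > 0 & !is.na(frac) & frac >= config$mcid_fraction)
  data.frame(improvement_frac = frac,
             mcid = mcid,
             complete_relief = nps_6wk == 0)
}

#' Per-patient metric table
#'
#' Applies the three quantification metrics (percentage change, TRR, TE) and
#' the pain outcomes to every patient under one aggregation strategy.
#'
#' @param cohort an `mmg_cohort`.
#' @param config a [metric_config()].
#' @return data.frame, one row per patient: `patient_id`, `region`,
#'   `n_nerves`, `mean_pre_mA`, `mean_post_mA`, `pct_change`, `trr`, `te`,
#'   `nps_pre`, `nps_6wk`, `pain_improvement_frac`, `mcid`,
#'   `complete_relief`, `aggregation_used`. `trr` and
#'   `pain_improvement_frac` are `NA` where undefined.
#' @export
compute_metrics <- function(cohort, config = metric_config()) {
  stopifnot(inherits(cohort, "mmg_cohort"))
  pt <- cohort$patients
  rows <- lapply(seq_len(nrow(pt)), function(i) {
    nv <- patient_nerves(cohort, pt$patient_id[i])
    data.frame(
      patient_id = pt$patient_id[i],
      region = pt$region[i],
      n_nerves = nrow(nv),
      mean_pre_mA = mean(nv$pre_mA),
      mean_post_mA = mean(nv$post_mA),
      pct_change = patient_pct_change(nv$pre_mA, nv$post_mA,
                                      config$aggregation),
      trr = patient_trr(nv$pre_mA, nv$post_mA, config$reference_mA),
      te = patient_te(nv$pre_mA, nv$post_mA, config$reference_mA,
                      config$aggregation),
      nps_pre = pt$nps_pre[i],
      nps_6wk = pt$nps_6wk[i],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  po <- pain_outcomes(out$nps_pre, out$nps_6wk, config)
  out$pain_improvement_frac <- po$improvement_frac
  out$mcid <- po$mcid
  out$complete_relief <- po$complete_relief
  out$aggregation_used <- config$aggregation
  rownames(out) <- NULL
  out
}

#' Nerve-level threshold-change summary
#'
#' Counts and moments over all nerves pooled across patients: how many had
#' elevated baselines (`pre > reference`), how many of those improved by at
#' least the stimulator increment, how many improvers normalized to at or
#' below the reference, and how many worsened; plus mean and SD of pre, post
#' and reduction. Two percentage-improvement figures are reported and
#' labeled: the mean of per-nerve percentage reductions
#' (`mean_pct_reduction`, computed over elevated nerves) and the
#' ratio-of-means `pooled_pct_reduction = (mean pre - mean post)/mean pre`.
#'
#' @inheritParams compute_metrics
#' @return list of class `mmg_nerve_summary`.
#' @export
nerve_level_summary <- function(cohort, config = metric_config()) {
  stopifnot(inherits(cohort, "mmg_cohort"))
  nv <- cohort$nerves
  R <- config$reference_mA
  elevated <- nv$pre_mA > R
  reduction <- nv$pre_mA - nv$post_mA
  improved <- elevated & reduction >= config$min_improvement_mA
  normalized <- improved & nv$post_mA <= R
  structure(list(
    n_nerves = nrow(nv),
    n_elevated = sum(elevated),
    n_improved = sum(improved),
    n_normalized = sum(normalized),
    n_worsened = sum(nv$post_mA > nv$pre_mA),
    mean_pre = mean(nv$pre_mA), sd_pre = stats::sd(nv$pre_mA),
    mean_post = mean(nv$post_mA), sd_post = stats::sd(nv$post_mA),
    mean_reduction = mean(reduction), sd_reduction = stats::sd(reduction),
    mean_pct_reduction = mean(reduction[elevated] / nv$pre_mA[elevated]),
    pooled_pct_reduction = (mean(nv$pre_mA) - mean(nv$post_mA)) /
      mean(nv$pre_mA),
    reference_mA = R,
    min_improvement_mA = config$min_improvement_mA
  ), class = "mmg_nerve_summary")
}

#' @export
print.mmg_nerve_summary <- function(x, ...) {
  cat("Nerve-level threshold changes (n = ", x$n_nerves, ")\n", sep = "")
  cat(sprintf("  elevated > %.1f mA : %d/%d (%.1f%%)\n", x$reference_mA,
              x$n_elevated, x$n_nerves, 100 * x$n_elevated / x$n_nerves))
  cat(sprintf("  improved >= %.0f mA: %d/%d of elevated\n",
              x$min_improvement_mA, x$n_improved, x$n_elevated))
  cat(sprintf("  normalized <= %.1f : %d/%d of improvers\n", x$reference_mA,
              x$n_normalized, x$n_improved))
  cat(sprintf("  worsened          : %d\n", x$n_worsened))
  cat(sprintf("  pre  %.2f +/- %.2f mA, post %.2f +/- %.2f mA\n",
              x$mean_pre, x$sd_pre, x$mean_post, x$sd_post))
  cat(sprintf("  reduction %.2f +/- %.2f mA (per-nerve mean %.1f%%, pooled %.1f%%)\n",
              x$mean_reduction, x$sd_reduction,
              100 * x$mean_pct_reduction, 100 * x$pooled_pct_reduction))
  invisible(x)
}
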