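#' Define an ordered set of metric strata
#'
#' A stratum specification is a list of ordered, disjoint, exhaustive
#' intervals over a metric's range, each with explicit boundary inclusivity,
#' so that point categories (e.g. "TRR exactly 1") and half-open ranges can
#' coexist.
#'
#' @param metric_name metric column the strata apply to.
#' @param lo,hi numeric vectors of interval bounds (use `-Inf`/`Inf` for
#'   open ends).
#' @param lo_closed,hi_closed logical vectors: is each bound included?
#' @param labels character labels, emitted in the given order.
#' @return data.frame of class `mmg_strata_spec`.
#' @export
stratum_spec <- function(metric_name, lo, hi, lo_closed, hi_closed, labels) {
  stopifnot(length(lo) == length(hi), length(lo) == length(labels),
            length(lo) == length(lo_closed), length(lo) == length(hi_closed),
            all(lo <= hi))
  out <- data.frame(label = labels, lo = lo, hi = hi,
                    lo_closed = lo_closed, hi_closed = hi_closed,
                    stringsAsFactors = FALSE)
  attr(out, "metric_name") <- metric_name
  class(out) <- c("mmg_strata_spec", "data.frame")
  out
}

#' Default TRR strata
#'
#' Complete normalization (TRR exactly 1), substantial reduction
#' (0.6 <= TRR < 1) and partial reduction (TRR < 0.6).
#' @return an [stratum_spec()].
#' @export
trr_default_strata <- function() {
  stratum_spec("trr",
               lo = c(1, 0.6, -Inf), hi = c(1, 1, 0.6),
               lo_closed = c(TRUE, TRUE, FALSE),
               hi_closed = c(TRUE, FALSE, FALSE),
               labels = c("TRR = 1.0 (complete normalization)",
                          "0.6 <= TRR < 1.0 (substantial reduction)",
                          "TRR < 0.6 (partial reduction)"))
}

#' Default TE strata
#'
#' At/near reference (TE < 0.5 mA), moderate excess (0.5--2.5 mA) and
#' substantial excess (>= 2.5 mA).
#' @return an [stratum_spec()].
#' @export
te_default_strata <- function() {
  stratum_spec("te",
               lo = c(0, 0.5, 2.5), hi = c(0.5, 2.5, Inf),
               lo_closed = c(TRUE, TRUE, TRUE),
               hi_closed = c(FALSE, FALSE, TRUE),
               labels = c("0.0 <= TE < 0.5 mA (at/near reference)",
                          "0.5 <= TE < 2.5 mA (moderate excess)",
                          "TE >= 2.5 mA (substantial excess)"))
}

in_stratum <- function(x, spec_row) {
  lo_ok <- if (spec_row$lo_closed) x >= spec_row$lo else x > spec_row$lo
  hi_ok <- if (spec_row$hi_closed) x <= spec_row$hi else x < spec_row$hi
  lo_ok & hi_ok
}

#' Stratified outcome table
#'
#' Assigns each analyzed patient (defined stratifying metric and defined
#' pain-improvement fraction) to a stratum and summarizes each category:
#' patient count, mean improvement fraction with a Student-t 95% interval
#' (`n - 1` df), and the complete-relief rate with its Wilson 95% interval.
#' Categories are emitted in specification order; a patient falling in no
#' category is an error (the specification must be exhaustive).
#'
#' @param metrics output of [compute_metrics()].
#' @param spec an [stratum_spec()].
#' @return data.frame of class `mmg_strata`: `label`, `n`,
#'   `mean_improvement`, `improvement_lo`, `improvement_hi`, `relief_k`,
#'   `relief_rate`, `relief_lo`, `relief_hi`.
#' @export
stratify <- function(metrics, spec) {
  stopifnot(inherits(spec, "mmg_strata_spec"))
  col <- attr(spec, "metric_name")
  stopifnot(col %in% names(metrics))
  m <- metrics[!is.na(metrics[[col]]) & !is.na(metrics$pain_improvement_frac),
               , drop = FALSE]
  x <- m[[col]]

  assigned <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(spec))) {
    hit <- in_stratum(x, spec[i, ]) & is.na(assigned)
    assigned[hit] <- i
  }
  if (anyNA(assigned)) {
    stop("stratum specification does not cover value(s): ",
         paste(unique(x[is.na(assigned)]), collapse = ", "), call. = FALSE)
  }

  rows <- lapply(seq_len(nrow(spec)), function(i) {
    sub <- m[assigned == i, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) {
      return(data.frame(label = spec$label[i], n = 0L,
                        mean_improvement = NA_real_,
                        improvement_lo = NA_real_, improvement_hi = NA_real_,
                        relief_k = 0L, relief_rate = NA_real_,
                        relief_lo = NA_real_, relief_hi = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mu <- mean(sub$pain_improvement_frac)
    half <- if (n > 1) {
      stats::qt(0.975, n - 1) * stats::sd(sub$pain_improvement_frac) / sqrt(n)
    } else {
      NA_real_
    }
    k <- sum(sub$complete_relief)
    w <- wilson_interval(k, n)
    data.frame(label = spec$label[i], n = n,
               mean_improvement = mu,
               improvement_lo = mu - half, improvement_hi = mu + half,
               relief_k = k, relief_rate = k / n,
               relief_lo = w$lo, relief_hi = w$hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mmg_strata", "data.frame")
  out
}

#' Sufficiency-plateau check below the reference
#'
#' Among patients who reached the reference (TE = 0, i.e. mean
#' post-decompression threshold at or below it), tests whether further
#' threshold reduction is associated with additional pain improvement:
#' Pearson correlation of the mean post threshold with the improvement
#' fraction within that subset. A near-zero correlation supports treating
#' the reference as a functional sufficiency plateau.
#'
#' @param metrics output of [compute_metrics()].
#' @param reference_mA physiologic reference, default 2.0 mA.
#' @return an `mmg_cor` (see [pearson_with_ci()]); its `n` is the subset
#'   size.
#' @export
plateau_check <- function(metrics, reference_mA = 2.0) {
  sub <- metrics[!is.na(metrics$te) & metrics$te == 0 &
                   !is.na(metrics$pain_improvement_frac), , drop = FALSE]
  if (nrow(sub) < 4) {
    stop("insufficient data: fewer than 4 patients at the reference",
         call. = FALSE)
  }
  pearson_with_ci(sub$mean_post_mA, sub$pain_improvement_frac)
}

#' Cut-point screening on the post-decompression threshold
#'
#' For each candidate cutoff `c` classifies a patient as test-positive when
#' the mean post-decompression threshold is `<= c` (equivalently TE at most
#' `c - reference`) and tabulates sensitivity, specificity, PPV and NPV
#' against a chosen binary outcome. The outcome must be named explicitly
#' (`complete_relief`, `mcid` or `any_improvement`); the scan also reports
#' the empirical AUC by the rank (Mann-Whitney) statistic, with ties
#' counted as half.
#'
#' @param metrics output of [compute_metrics()].
#' @param outcome_name `"complete_relief"`, `"mcid"` or `"any_improvement"`
#'   (improvement fraction > 0).
#' @param cutoffs candidate cutoffs in mA; default: midpoints between sorted
#'   unique observed mean post thresholds, plus the reference itself.
#' @param reference_mA physiologic reference, default 2.0 mA.
#' @return data.frame of class `mmg_cutpoints` with one row per cutoff
#'   (`cutoff_mA`, `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `n_positive_test`) and attributes `auc` and
#'   `outcome_name`.
#' @export
cutpoint_scan <- function(metrics,
                          outcome_name = c("complete_relief", "mcid",
                                           "any_improvement"),
                          cutoffs = NULL, reference_mA = 2.0) {
  outcome_name <- match.arg(outcome_name)
  m <- metrics[!is.na(metrics$pain_improvement_frac), , drop = FALSE]
  y <- switch(outcome_name,
              complete_relief = m$complete_relief,
              mcid = m$mcid,
              any_improvement = m$pain_improvement_frac > 0)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: only one class present", call. = FALSE)
  }
  post <- m$mean_post_mA
  if (is.null(cutoffs)) {
    u <- sort(unique(post))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
    cutoffs <- sort(unique(c(u[1] - 0.5, mids, u[length(u)] + 0.5,
                             reference_mA)))
  }

  rows <- lapply(cutoffs, function(cc) {
    test_pos <- post <= cc
    tp <- sum(test_pos & y); fp <- sum(test_pos & !y)
    fn <- sum(!test_pos & y); tn <- sum(!test_pos & !y)
    data.frame(cutoff_mA = cc, tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               n_positive_test = tp + fp)
  })
  out <- do.call(rbind, rows)

  # rank AUC of (-post) as a score for the positive class; ties get 1/2
  pos <- -post[y]; neg <- -post[!y]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  attr(out, "auc") <- mean(cmp)
  attr(out, "outcome_name") <- outcome_name
  attr(out, "reference_mA") <- reference_mA
  class(out) <- c("mmg_cutpoints", "data.frame")
  out
}
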