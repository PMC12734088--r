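# Cross-validation of the simple metric -> outcome linear models.
#
# Per-fold fits use downdated sufficient statistics (totals minus the held-out
# fold), which is algebraically identical to refitting OLS on the remaining
# observations and keeps LOOCV at n = 2000 instantaneous. Held-out
# predictions and per-fold slopes are stored so every summary can be audited
# against a brute-force recomputation.

cv_core <- function(x, y, folds, method, n_folds) {
  n <- length(x)
  Sx <- sum(x); Sy <- sum(y); Sxx <- sum(x^2); Sxy <- sum(x * y)
  pred <- numeric(n)
  slopes <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    idx <- which(folds == f)
    m <- n - length(idx)
    sx <- Sx - sum(x[idx]); sy <- Sy - sum(y[idx])
    sxx <- Sxx - sum(x[idx]^2); sxy <- Sxy - sum(x[idx] * y[idx])
    denom <- m * sxx - sx^2
    if (m < 2 || abs(denom) < 1e-12 * max(1, m * sxx)) {
      stop("degenerate fold ", f, ": constant predictor in training set",
           call. = FALSE)
    }
    slope <- (m * sxy - sx * sy) / denom
    intercept <- (sy - slope * sx) / m
    slopes[f] <- slope
    pred[idx] <- intercept + slope * x[idx]
  }
  apparent_r <- stats::cor(x, y)
  cv_r <- stats::cor(y, pred)
  rmse <- sqrt(mean((y - pred)^2))
  structure(list(
    metric_name = NA_character_,
    method = method,
    apparent_r = apparent_r,
    cv_r = cv_r,
    shrinkage_pct = if (apparent_r != 0)
      100 * (abs(apparent_r) - cv_r) / abs(apparent_r) else NA_real_,
    apparent_r2 = apparent_r^2,
    cv_r2 = cv_r^2,
    r2_loss_pct = if (apparent_r != 0)
      100 * (apparent_r^2 - cv_r^2) / apparent_r^2 else NA_real_,
    rmse = rmse,
    loocv_beta = mean(slopes),
    n = n,
    predictions = pred,
    fold_slopes = slopes,
    folds = folds
  ), class = "mmg_cv")
}

#' Leave-one-out cross-validation of a simple linear model
#'
#' For each observation, an OLS line is fitted to the other `n - 1` pairs and
#' used to predict the held-out outcome. The cross-validated correlation
#' `cv_r` is the Pearson correlation between actual outcomes and these
#' held-out predictions; shrinkage is the percentage decrease from the
#' apparent (full-data) performance,
#' `100 (|apparent_r| - cv_r)/|apparent_r|`. (Held-out predictions correlate
#' positively with outcomes whenever the model carries signal, whatever the
#' sign of the predictor's own correlation, so the apparent side enters as a
#' magnitude.)
#' `cv_r2` is defined as `cv_r^2`. `rmse` is the root-mean-square held-out
#' prediction error and `loocv_beta` the mean of the `n` per-fold slopes.
#' The procedure is fully deterministic.
#'
#' @param x predictor values (a patient-level metric).
#' @param y outcome values (pain-improvement fractions).
#' @return object of class `mmg_cv` with fields `apparent_r`, `cv_r`,
#'   `shrinkage_pct`, `apparent_r2`, `cv_r2`, `r2_loss_pct`, `rmse`,
#'   `loocv_beta`, `n`, plus per-fold `predictions`, `fold_slopes` and the
#'   fold assignment for audit.
#' @export
loocv_linear <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("insufficient data: n >= 5 required", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  cv_core(x, y, folds = seq_len(n), method = "loocv", n_folds = n)
}

#' k-fold cross-validation of a simple linear model
#'
#' Seeded random partition into `k` near-equal folds, stratified by outcome
#' above/below the median to reduce partition variance; otherwise identical
#' in its statistics to [loocv_linear()]. With `k = n` the partition reduces
#' to leave-one-out and the result is identical to `loocv_linear`.
#'
#' @inheritParams loocv_linear
#' @param k number of folds, `2 <= k <= n`.
#' @param seed RNG seed controlling the fold assignment (recorded in the
#'   result).
#' @return an `mmg_cv` object (see [loocv_linear()]); `folds` records the
#'   assignment.
#' @export
kfold_linear <- function(x, y, k = 5, seed = 17) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("insufficient data: n >= 5 required", call. = FALSE)
  if (k < 2 || k > n) {
    stop("configuration error: k must satisfy 2 <= k <= n", call. = FALSE)
  }
  if (k == n) {
    folds <- seq_len(n)
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    folds <- integer(n)
    for (stratum in list(which(y <= stats::median(y)),
                         which(y > stats::median(y)))) {
      if (length(stratum)) {
        shuffled <- sample(stratum)
        folds[shuffled] <- rep_len(sample.int(k), length(shuffled))
      }
    }
  }
  out <- cv_core(x, y, folds = folds, method = if (k == n) "loocv" else "kfold",
                 n_folds = max(folds))
  out$k <- k
  out$seed <- if (k == n) NA_integer_ else seed
  out
}

#' @export
print.mmg_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation%s, n = %d\n",
              toupper(x$method),
              if (!is.na(x$metric_name)) paste0(" of ", x$metric_name) else "",
              x$n))
  cat(sprintf("  apparent r = %.3f, cv r = %.3f, shrinkage = %.1f%%\n",
              x$apparent_r, x$cv_r, x$shrinkage_pct))
  cat(sprintf("  apparent R^2 = %.3f, cv R^2 = %.3f (loss %.1f%%)\n",
              x$apparent_r2, x$cv_r2, x$r2_loss_pct))
  cat(sprintf("  RMSE = %.3f, mean per-fold slope = %.4f\n",
              x$rmse, x$loocv_beta))
  invisible(x)
}

#' Cross-validate all three quantification metrics
#'
#' Runs [loocv_linear()] of the pain-improvement fraction on each metric
#' under the same exclusion rules as the apparent analysis: TRR on the
#' subset of patients where it is defined, percentage change and TE on all
#' patients with baseline pain. Results are returned ranked by `|cv_r|`.
#'
#' @param metrics output of [compute_metrics()].
#' @param metric_names which metric columns to cross-validate.
#' @return list of `mmg_cv` objects, named by metric, ordered by decreasing
#'   `|cv_r|`; the ranking is also attached as attribute `ranking`.
#' @export
compare_metrics_cv <- function(metrics,
                               metric_names = c("trr", "pct_change", "te")) {
  stopifnot(all(metric_names %in% names(metrics)))
  res <- lapply(metric_names, function(nm) {
    keep <- !is.na(metrics[[nm]]) & !is.na(metrics$pain_improvement_frac)
    cv <- loocv_linear(metrics[[nm]][keep],
                       metrics$pain_improvement_frac[keep])
    cv$metric_name <- nm
    cv
  })
  names(res) <- metric_names
  ord <- order(-abs(vapply(res, `[[`, numeric(1), "cv_r")))
  res <- res[ord]
  attr(res, "ranking") <- names(res)
  res
}
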