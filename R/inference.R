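# Confidence level is fixed at 95% throughout; z carried at full precision,
# rounding to display precision happens only in formatting.
Z975 <- 1.959964

#' Fisher-z confidence interval for a correlation
#'
#' Closed-form 95% interval `tanh(atanh(r) +/- z / sqrt(n - 3))` and the
#' two-sided p-value from `t = r sqrt(n-2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. Usable directly on a reported `(r, n)` pair without
#' the underlying data.
#'
#' @param r Pearson correlation in (-1, 1).
#' @param n sample size, at least 4.
#' @return list with `r`, `n`, `ci_lo`, `ci_hi`, `p`.
#' @export
#' @examples
#' cor_fisher_ci(0.656, 38)
cor_fisher_ci <- function(r, n) {
  if (n < 4) stop("insufficient data: n >= 4 required", call. = FALSE)
  if (abs(r) >= 1) stop("r must lie strictly within (-1, 1)", call. = FALSE)
  ci <- tanh(atanh(r) + c(-1, 1) * Z975 / sqrt(n - 3))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, n = n, ci_lo = ci[1], ci_hi = ci[2],
       p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Pearson correlation with Fisher-z interval
#'
#' Product-moment correlation of two samples with the [cor_fisher_ci()]
#' interval and t-based two-sided p-value.
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite, each with
#'   nonzero variance.
#' @return object of class `mmg_cor`: list with `r`, `n`, `ci_lo`, `ci_hi`,
#'   `p`.
#' @export
pearson_with_ci <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("insufficient data: n >= 4 required", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  out <- cor_fisher_ci(r, n)
  class(out) <- "mmg_cor"
  out
}

#' @export
print.mmg_cor <- function(x, ...) {
  cat(sprintf("r = %.3f (95%% CI %.3f to %.3f), n = %d, p = %.4g\n",
              x$r, x$ci_lo, x$ci_hi, x$n, x$p))
  invisible(x)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Compares `r1y = cor(x1, y)` against `r2y = cor(x2, y)` measured on the
#' same `n` subjects, accounting for their covariance through `r12 =
#' cor(x1, x2)`. With `rbar = (r1y + r2y)/2` and
#' \deqn{c = \frac{r_{12}(1 - 2\bar r^2) - \tfrac12 \bar r^2
#'   (1 - 2\bar r^2 - r_{12}^2)}{(1 - \bar r^2)^2}}
#' the statistic is
#' `Z = (atanh(r1y) - atanh(r2y)) * sqrt(n - 3) / sqrt(2 - 2c)`, referred to
#' the standard normal (two-sided).
#'
#' @param r1y,r2y correlations of the two competing predictors with the
#'   shared outcome, each in (-1, 1).
#' @param r12 correlation between the two predictors, in (-1, 1).
#' @param n common sample size, at least 4.
#' @return list with `z` and `p`.
#' @export
steiger_test <- function(r1y, r2y, r12, n) {
  if (n < 4) stop("insufficient data: n >= 4 required", call. = FALSE)
  if (any(abs(c(r1y, r2y, r12)) >= 1)) {
    stop("correlations must lie strictly within (-1, 1)", call. = FALSE)
  }
  rbar <- (r1y + r2y) / 2
  cnum <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  cc <- cnum / (1 - rbar^2)^2
  if (abs(cc) >= 1) {
    stop("numeric degeneracy: |c| >= 1 in Steiger covariance term",
         call. = FALSE)
  }
  z <- (atanh(r1y) - atanh(r2y)) * sqrt(n - 3) / sqrt(2 - 2 * cc)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Ordinary least squares with t-based intervals
#'
#' Wrapper around [stats::lm()] returning the coefficient table with
#' standard errors, 95% t-intervals (`n - p` df), two-sided p-values, R^2,
#' n and Gaussian AIC, as used for the dose-response models.
#'
#' @param y numeric outcome vector.
#' @param x data.frame (or matrix) of predictor columns; an intercept is
#'   always included.
#' @return object of class `mmg_ols`: list with `coefficients` (data.frame
#'   `term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p`), `r_squared`, `n`,
#'   `aic`, and the underlying `fit`.
#' @export
ols_fit <- function(y, x) {
  x <- as.data.frame(x)
  stopifnot(length(y) == nrow(x))
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(x) + 1L) {
    stop("insufficient data: n must exceed number of coefficients",
         call. = FALSE)
  }
  dat <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: collinear column(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 n = n,
                 aic = stats::AIC(fit),
                 fit = fit),
            class = "mmg_ols")
}

#' @export
print.mmg_ols <- function(x, ...) {
  cat(sprintf("OLS fit, n = %d, R^2 = %.3f, AIC = %.2f\n",
              x$n, x$r_squared, x$aic))
  print(within(x$coefficients, {
    estimate <- round(estimate, 4); se <- round(se, 4)
    ci_lo <- round(ci_lo, 4); ci_hi <- round(ci_hi, 4)
    p <- signif(p, 3)
  }), row.names = FALSE)
  invisible(x)
}

#' Covariate-adjusted TRR model
#'
#' Regresses the pain-improvement fraction on patient TRR adjusted for
#' baseline pain, number of nerves and anatomical region (lumbar indicator).
#' Patients with undefined TRR or improvement fraction are excluded.
#'
#' @param metrics output of [compute_metrics()].
#' @return an [ols_fit()] result; the `trr` row is the adjusted effect.
#' @export
adjusted_trr_model <- function(metrics) {
  keep <- !is.na(metrics$trr) & !is.na(metrics$pain_improvement_frac)
  m <- metrics[keep, , drop = FALSE]
  ols_fit(m$pain_improvement_frac,
          data.frame(trr = m$trr,
                     nps_pre = m$nps_pre,
                     n_nerves = m$n_nerves,
                     region_lumbar = as.integer(m$region == "lumbar")))
}

#' Logistic dose-response with Wald and bootstrap intervals
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' predictor (binomial IRLS via [stats::glm()], coefficient tolerance 1e-8,
#' at most 100 iterations). Reports the odds ratio per unit predictor with
#' its Wald interval `exp(slope +/- z * SE)`, a seeded percentile bootstrap
#' interval over patient-level resamples, the Wald p-value and the model
#' AIC.
#'
#' @param outcome logical or 0/1 vector; both classes must be present.
#' @param predictor numeric vector.
#' @param bootstrap_reps number of patient-level resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `mmg_logit`: list with `or_per_unit`,
#'   `wald_ci_lo`, `wald_ci_hi`, `bootstrap_ci_lo`, `bootstrap_ci_hi`, `p`,
#'   `aic`, `coefficients` (intercept, slope), `n` and
#'   `predicted_probability` (a function of predictor values).
#' @export
logistic_fit <- function(outcome, predictor, bootstrap_reps = 2000,
                         seed = 17) {
  outcome <- as.integer(outcome)
  keep <- stats::complete.cases(outcome, predictor)
  outcome <- outcome[keep]; predictor <- predictor[keep]
  n <- length(outcome)
  if (n < 10) stop("insufficient data: n >= 10 required", call. = FALSE)
  if (length(unique(outcome)) < 2L) {
    stop("degenerate outcome: only one class present", call. = FALSE)
  }
  if (stats::sd(predictor) == 0) {
    # likelihood is flat in the slope: report the null per-unit effect
    p0 <- mean(outcome)
    return(structure(list(
      or_per_unit = 1, wald_ci_lo = NA_real_, wald_ci_hi = NA_real_,
      bootstrap_ci_lo = NA_real_, bootstrap_ci_hi = NA_real_,
      p = 1,
      aic = -2 * sum(stats::dbinom(outcome, 1, p0, log = TRUE)) + 2,
      coefficients = c(stats::qlogis(p0), 0), n = n,
      bootstrap_reps = 0L, seed = seed,
      predicted_probability = function(x) rep(p0, length(x))
    ), class = "mmg_logit"))
  }

  fit_one <- function(y, x) {
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  }
  fit <- withCallingHandlers(
    fit_one(outcome, predictor),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("complete separation: logistic fit degenerate", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || abs(stats::coef(fit)[2]) > 50) {
    stop("complete separation: logistic fit did not converge", call. = FALSE)
  }

  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[2]
  or <- exp(beta[2])
  wald <- exp(beta[2] + c(-1, 1) * Z975 * se)
  p <- 2 * stats::pnorm(-abs(beta[2] / se))

  boot_or <- rep(NA_real_, bootstrap_reps)
  if (bootstrap_reps > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- outcome[idx]; xb <- predictor[idx]
      if (length(unique(yb)) < 2L || stats::sd(xb) == 0) next
      bfit <- tryCatch(suppressWarnings(fit_one(yb, xb)),
                       error = function(e) NULL)
      if (!is.null(bfit) && bfit$converged && abs(stats::coef(bfit)[2]) < 50) {
        boot_or[b] <- exp(stats::coef(bfit)[2])
      }
    }
  }
  bci <- if (all(is.na(boot_or))) c(NA_real_, NA_real_) else
    stats::quantile(boot_or, c(0.025, 0.975), na.rm = TRUE, names = FALSE)

  structure(list(
    or_per_unit = unname(or),
    wald_ci_lo = wald[1], wald_ci_hi = wald[2],
    bootstrap_ci_lo = bci[1], bootstrap_ci_hi = bci[2],
    p = unname(p),
    aic = stats::AIC(fit),
    coefficients = unname(beta),
    n = n,
    bootstrap_reps = bootstrap_reps,
    seed = seed,
    predicted_probability = function(x) {
      stats::plogis(beta[1] + beta[2] * x)
    }
  ), class = "mmg_logit")
}

#' @export
print.mmg_logit <- function(x, ...) {
  cat(sprintf("Logistic fit, n = %d, AIC = %.2f\n", x$n, x$aic))
  cat(sprintf("  OR per unit = %.3f (Wald 95%% CI %.3f-%.3f; bootstrap %.3f-%.3f), p = %.4g\n",
              x$or_per_unit, x$wald_ci_lo, x$wald_ci_hi,
              x$bootstrap_ci_lo, x$bootstrap_ci_hi, x$p))
  invisible(x)
}

#' 2x2 odds ratio with exact test
#'
#' Sample odds ratio `(a d)/(b c)` for the table
#' `rbind(c(a, b), c(c, d))` (rows = exposure, columns = outcome), with a
#' two-sided exact p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities no greater than the
#' observed table's (the usual two-sided Fisher convention). When any cell
#' is zero the odds ratio is reported with the Haldane-Anscombe 0.5
#' continuity correction and flagged.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return list of class `mmg_or2x2` with `a,b,c,d`, `odds_ratio`,
#'   `exact_p`, `corrected` (logical), `method`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("undefined margin: a row or column sum is zero", call. = FALSE)
  }
  corrected <- any(counts == 0)
  or <- if (corrected) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }

  # exact two-sided p: hypergeometric mass summation at fixed margins
  m <- a + b          # exposed row total
  nn <- c + d         # unexposed row total
  k <- a + c          # outcome column total
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  exact_p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  structure(list(a = a, b = b, c = c, d = d,
                 odds_ratio = or, exact_p = exact_p,
                 corrected = corrected,
                 method = paste0(
                   if (corrected) "Haldane-Anscombe corrected OR; " else "",
                   "two-sided exact p by hypergeometric mass summation")),
            class = "mmg_or2x2")
}

#' @export
print.mmg_or2x2 <- function(x, ...) {
  cat(sprintf("2x2 table [%d %d; %d %d]: OR = %.3f%s, exact p = %.4g\n",
              x$a, x$b, x$c, x$d, x$odds_ratio,
              if (x$corrected) " (0.5-corrected)" else "", x$exact_p))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' 95% interval from inverting the score test:
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}
#'   {1 + z^2/n}}
#' Well-behaved at small n and at the 0/1 boundaries.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @return list with `k`, `n`, `point`, `lo`, `hi`.
#' @export
#' @examples
#' wilson_interval(13, 17)
wilson_interval <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  p <- k / n
  z <- Z975
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  list(k = k, n = n, point = p,
       lo = max(0, (centre - half) / denom),
       hi = min(1, (centre + half) / denom))
}
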