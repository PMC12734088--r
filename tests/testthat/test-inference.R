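test_that("Fisher-z machinery matches cor.test on random samples", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- pearson_with_ci(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
    # interval contains r and stays inside [-1, 1]
    expect_true(res$ci_lo <= res$r && res$r <= res$ci_hi)
    expect_true(res$ci_lo >= -1 && res$ci_hi <= 1)
  }
})

test_that("Fisher interval width shrinks to zero with n", {
  widths <- sapply(c(10, 100, 10000), function(n) {
    ci <- cor_fisher_ci(0.5, n); ci$ci_hi - ci$ci_lo
  })
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 0.05)
})

test_that("correlation machinery rejects degenerate input", {
  expect_error(pearson_with_ci(1:3, 1:3), "insufficient")
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(cor_fisher_ci(1, 30), "within")
})

test_that("Steiger Z is zero at equal correlations and antisymmetric", {
  res <- steiger_test(0.5, 0.5, 0.3, 40)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  a <- steiger_test(0.6, 0.3, 0.5, 50)
  b <- steiger_test(0.3, 0.6, 0.5, 50)
  expect_equal(a$z, -b$z)
  expect_error(steiger_test(0.5, 0.4, 1, 40), "within")
})

test_that("Steiger Z agrees with an independent transcription of the statistic", {
  # separate hand-coded transcription of the dependent-correlation z-test
  oracle <- function(rjk, rhk, rjh, n) {
    rbar2 <- ((rjk + rhk) / 2)^2
    cov_term <- (rjh * (1 - 2 * rbar2) -
                   0.5 * rbar2 * (1 - 2 * rbar2 - rjh^2)) / (1 - rbar2)^2
    (0.5 * log((1 + rjk) / (1 - rjk)) -
        0.5 * log((1 + rhk) / (1 - rhk))) /
      sqrt((2 - 2 * cov_term) / (n - 3))
  }
  cases <- rbind(c(0.6, 0.3, 0.5, 50), c(0.656, 0.494, 0.4, 38),
                 c(-0.2, 0.4, 0.1, 25))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(steiger_test(cs[1], cs[2], cs[3], cs[4])$z,
                 oracle(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-12)
  }
})

test_that("Steiger test holds its size under the dependent null", {
  # trivariate normal with equal predictor-outcome correlations
  Sig <- matrix(c(1, 0.5, 0.4,
                  0.5, 1, 0.4,
                  0.4, 0.4, 1), 3)
  L <- chol(Sig)
  set.seed(99)
  n <- 60
  rej <- replicate(1500, {
    d <- matrix(rnorm(3 * n), n) %*% L
    res <- steiger_test(cor(d[, 1], d[, 3]), cor(d[, 2], d[, 3]),
                        cor(d[, 1], d[, 2]), n)
    res$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("OLS recovers noise-free coefficients to machine precision", {
  x <- seq(0, 7, length.out = 30)
  # lm warns about the perfect fit; the exact recovery is the point here
  fit <- suppressWarnings(ols_fit(1 - 0.063 * x, data.frame(te = x)))
  sl <- fit$coefficients[fit$coefficients$term == "te", ]
  expect_equal(sl$estimate, -0.063, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("OLS flags collinear designs and rewards a truly predictive column", {
  x <- rnorm(30)
  expect_error(ols_fit(rnorm(30), data.frame(a = x, b = 2 * x)), "singular")
  expect_error(ols_fit(rnorm(30), data.frame(a = rep(1, 30))), "singular")

  set.seed(5)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 * x1 + 0.4 * x2 + rnorm(n)
  expect_lt(ols_fit(y, data.frame(x1, x2))$aic,
            ols_fit(y, data.frame(x1))$aic)
})

test_that("adjusted TRR model keeps covariate null effects near zero", {
  set.seed(8)
  coh <- generate_cohort(synthetic_config(n_patients = 300), seed = 8)
  m <- compute_metrics(coh)
  fit <- adjusted_trr_model(m)
  cf <- fit$coefficients
  # improvement is generated from TE only; adjusted covariates stay null
  for (term in c("nps_pre", "n_nerves", "region_lumbar")) {
    row <- cf[cf$term == term, ]
    expect_true(row$ci_lo <= 0 && 0 <= row$ci_hi)
  }
  expect_gt(cf$estimate[cf$term == "trr"], 0)
})

test_that("logistic fit recovers a known per-unit odds ratio", {
  set.seed(12)
  n <- 500
  x <- runif(n, 0, 8)
  y <- rbinom(n, 1, plogis(0.7 + log(0.6) * x))
  fit <- logistic_fit(y, x)
  expect_true(fit$wald_ci_lo <= 0.6 && 0.6 <= fit$wald_ci_hi)
  expect_equal(fit$or_per_unit, 0.6, tolerance = 0.12)
  expect_true(fit$wald_ci_lo <= fit$or_per_unit &&
                fit$or_per_unit <= fit$wald_ci_hi)
})

test_that("logistic fit handles degenerate inputs per contract", {
  expect_equal(logistic_fit(rep(c(0, 1), 10), rep(3, 20),
                            bootstrap_reps = 0)$or_per_unit, 1)
  expect_error(logistic_fit(rep(1, 20), rnorm(20)), "one class")
  x <- c(1:10, 21:30)
  expect_error(logistic_fit(as.integer(x > 15), x, bootstrap_reps = 0),
               "separation")
})

test_that("bootstrap interval is seeded and reproducible", {
  set.seed(2)
  x <- runif(40, 0, 6)
  y <- rbinom(40, 1, plogis(1 - 0.5 * x))
  f1 <- logistic_fit(y, x, bootstrap_reps = 300, seed = 11)
  f2 <- logistic_fit(y, x, bootstrap_reps = 300, seed = 11)
  expect_identical(f1$bootstrap_ci_lo, f2$bootstrap_ci_lo)
  expect_true(f1$bootstrap_ci_lo < f1$or_per_unit)
})

test_that("2x2 odds ratio and exact p match reference cases", {
  res <- odds_ratio_2x2(13, 4, 8, 15)
  expect_equal(res$odds_ratio, 13 * 15 / (4 * 8))
  expect_equal(res$exact_p,
               fisher.test(rbind(c(13, 4), c(8, 15)))$p.value,
               tolerance = 1e-10)
  flat <- odds_ratio_2x2(1, 1, 1, 1)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$exact_p, 1)
  corr <- odds_ratio_2x2(5, 0, 2, 3)
  expect_true(corr$corrected)
  expect_equal(corr$odds_ratio, (5.5 * 3.5) / (0.5 * 2.5))
  expect_error(odds_ratio_2x2(0, 0, 2, 3), "margin")
  expect_error(odds_ratio_2x2(1.5, 2, 2, 3), "integer")
})

test_that("exact p agrees with fisher.test across random tables", {
  set.seed(31)
  for (i in 1:30) {
    tb <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    res <- odds_ratio_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(res$exact_p, fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("Wilson interval matches printed-style cases and boundaries", {
  w <- wilson_interval(13, 17)
  expect_equal(round(c(w$lo, w$hi), 3), c(0.527, 0.904))
  w2 <- wilson_interval(2, 8)
  expect_equal(round(c(w2$lo, w2$hi), 3), c(0.071, 0.591))
  expect_equal(wilson_interval(0, 10)$lo, 0)
  expect_equal(wilson_interval(10, 10)$hi, 1)
  w3 <- wilson_interval(5, 9)
  expect_true(w3$lo <= w3$point && w3$point <= w3$hi)
})
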