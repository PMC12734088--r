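test_that("strata are exhaustive, ordered, and sum to the analyzed cohort", {
  m <- compute_metrics(generate_cohort(synthetic_config(), seed = 10))
  st <- stratify(m, trr_default_strata())
  expect_equal(sum(st$n),
               sum(!is.na(m$trr) & !is.na(m$pain_improvement_frac)))
  st_te <- stratify(m, te_default_strata())
  expect_equal(sum(st_te$n), sum(!is.na(m$pain_improvement_frac)))
  expect_equal(st$label, trr_default_strata()$label)
})

test_that("point categories and half-open intervals assign correctly", {
  f <- fake_metrics(mean_post = c(2, 2, 3, 5), improvement = c(1, 0.9, 0.8, 0.2),
                    relief = c(TRUE, TRUE, FALSE, FALSE),
                    trr = c(1, 1, 0.6, 0.2))
  st <- stratify(f, trr_default_strata())
  expect_equal(st$n, c(2L, 1L, 1L))          # TRR exactly 1 is its own category
  expect_equal(st$relief_k, c(2L, 0L, 0L))
  # a gap in the specification is an error, not silent loss
  gappy <- stratum_spec("trr", lo = c(0.5, -Inf), hi = c(1, 0.2),
                        lo_closed = c(TRUE, FALSE), hi_closed = c(TRUE, FALSE),
                        labels = c("hi", "lo"))
  expect_error(stratify(f, gappy), "does not cover")
})

test_that("all patients in one category yields a single full stratum", {
  f <- fake_metrics(mean_post = c(5, 6, 7, 8, 9),
                    improvement = c(0.5, 0.4, 0.3, 0.2, 0.1),
                    relief = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  one <- stratum_spec("te", lo = -Inf, hi = Inf,
                      lo_closed = FALSE, hi_closed = FALSE, labels = "all")
  st <- stratify(f, one)
  expect_equal(st$n, 5L)
  w <- wilson_interval(1, 5)
  expect_equal(st$relief_lo, w$lo)
  expect_equal(st$relief_hi, w$hi)
  # t-interval of the mean improvement
  expect_equal(st$improvement_hi - st$mean_improvement,
               qt(0.975, 4) * sd(f$pain_improvement_frac) / sqrt(5))
})

test_that("a monotone TE gradient shows up as monotone stratified outcomes", {
  cfg <- synthetic_config(n_patients = 400)
  m <- compute_metrics(generate_cohort(cfg, seed = 20))
  st <- stratify(m, te_default_strata())
  expect_true(all(diff(st$mean_improvement) < 0))
})

test_that("plateau check requires and uses the at-reference subset", {
  f <- fake_metrics(mean_post = c(1, 1.5, 2, 2), improvement = c(1, 0.9, 0.8, 1),
                    relief = rep(TRUE, 4))
  res <- plateau_check(f)
  expect_equal(res$n, 4L)
  expect_error(plateau_check(f[1:3, ]), "insufficient")
  # patients above the reference never enter
  f2 <- rbind(f, fake_metrics(mean_post = 7, improvement = 0.1, relief = FALSE))
  expect_equal(plateau_check(f2)$n, 4L)
})

test_that("cut-point scan reproduces a hand-counted confusion matrix", {
  f <- fake_metrics(mean_post = c(1, 2, 3, 3, 4, 5),
                    improvement = c(1, 1, 1, 0.1, 0.1, 0.1),
                    relief = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cp <- cutpoint_scan(f, "complete_relief", cutoffs = 2.5)
  expect_equal(cp$tp, 2L); expect_equal(cp$fn, 1L)
  expect_equal(cp$fp, 0L); expect_equal(cp$tn, 3L)
  expect_equal(cp$sensitivity, 2 / 3)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$ppv, 1)
  expect_equal(cp$n_positive_test, 2L)
})

test_that("extreme cutoffs give the degenerate corners of the ROC", {
  f <- fake_metrics(mean_post = c(1, 2, 3, 4, 5, 6),
                    improvement = runif(6, 0.1, 1),
                    relief = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cp <- cutpoint_scan(f, "complete_relief", cutoffs = c(0.5, 10))
  expect_equal(cp$sensitivity, c(0, 1))
  expect_equal(cp$specificity, c(1, 0))
})

test_that("rank AUC equals the trapezoidal integral over an exhaustive scan", {
  set.seed(13)
  post <- sample(seq(1, 12, by = 0.5), 30, replace = TRUE)
  relief <- runif(30) < plogis(2 - 0.5 * post)
  if (length(unique(relief)) < 2) relief[1:2] <- c(TRUE, FALSE)
  f <- fake_metrics(post, runif(30, 0.05, 1), relief)
  cp <- cutpoint_scan(f, "complete_relief")
  fpr <- c(0, 1 - cp$specificity, 1)   # cutoffs ascend, so FPR ascends
  tpr <- c(0, cp$sensitivity, 1)
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(attr(cp, "auc"), trap, tolerance = 1e-9)
})

test_that("a perfect separator reaches AUC 1 with a perfect cutoff", {
  f <- fake_metrics(mean_post = c(1, 1.5, 2, 6, 7, 8, 1.2, 7.5, 1.8, 6.5),
                    improvement = rep(c(1, 0.1), 5),
                    relief = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                               TRUE, FALSE, TRUE, FALSE))
  cp <- cutpoint_scan(f, "complete_relief")
  expect_equal(attr(cp, "auc"), 1)
  expect_true(any(cp$sensitivity == 1 & cp$specificity == 1))
  expect_error(cutpoint_scan(fake_metrics(c(3, 4, 5, 6, 7), rep(0.5, 5),
                                          rep(TRUE, 5)), "complete_relief"),
               "one class")
})
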