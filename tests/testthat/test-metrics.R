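test_that("nerve TRR matches hand-computed cases and is NA without elevation", {
  expect_equal(nerve_trr(9, 9), 0)
  expect_equal(nerve_trr(8, 2), 1)
  expect_equal(nerve_trr(10, 6), 0.5)          # (8 - 4) / 8
  expect_true(is.na(nerve_trr(2, 1)))          # elevation exactly zero
  expect_true(is.na(nerve_trr(1.5, 1)))
  # worsening is informative, not clamped
  expect_lt(nerve_trr(5, 7), 0)
})

test_that("patient TRR averages only nerves with baseline elevation", {
  expect_equal(patient_trr(c(9, 6, 5), c(9, 6, 5)), 0)
  expect_equal(patient_trr(c(8, 10), c(2, 2)), 1)
  expect_equal(patient_trr(c(10, 2), c(6, 1)), 0.5)  # second nerve excluded
  expect_true(is.na(patient_trr(c(2, 1), c(2, 1))))
})

test_that("patient TE clamps at zero and respects aggregation", {
  expect_equal(patient_te(c(9, 6, 5), c(9, 6, 5)), mean(c(9, 6, 5)) - 2)
  expect_equal(patient_te(3, 1.5), 0)
  expect_equal(patient_te(c(5, 6), c(3, 4)), 1.5)
  # index = argmax pre, worst = argmax post
  expect_equal(patient_te(c(9, 6), c(3, 6), aggregation = "index"), 1)
  expect_equal(patient_te(c(9, 6), c(3, 6), aggregation = "worst"), 4)
})

test_that("percentage change is reduction over aggregated baseline", {
  expect_equal(patient_pct_change(8.5, 3.4), (8.5 - 3.4) / 8.5)
  expect_equal(patient_pct_change(c(4, 8), c(4, 8)), 0)
  expect_equal(patient_pct_change(6, 3), 0.5)
  expect_equal(patient_pct_change(c(9, 6), c(3, 6), aggregation = "index"),
               (9 - 3) / 9)
})

test_that("nerve selection breaks ties by first occurrence", {
  expect_equal(select_nerve(c(9, 6), c(3, 6), "index"), 1L)
  expect_equal(select_nerve(c(9, 6), c(3, 6), "worst"), 2L)
  expect_equal(select_nerve(c(7, 7), c(3, 5), "index"), 1L)
  expect_equal(select_nerve(5, 2, "worst"), 1L)
})

test_that("pain outcomes implement the two-arm MCID rule", {
  po <- pain_outcomes(c(6, 8, 3, 0), c(6, 0, 2, 0))
  expect_equal(po$improvement_frac, c(0, 1, 1 / 3, NA))
  # 1-point drop from 3 is below 2 points but 33% >= 30%: MCID by the OR rule
  expect_equal(po$mcid, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(po$complete_relief, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("metric invariants hold on random threshold pairs", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    pre <- runif(k, 0.5, 25)
    post <- runif(k, 0.5, 25)
    r <- nerve_trr(pre, post)
    expect_true(all(r[!is.na(r)] <= 1))
    expect_gte(patient_te(pre, post), 0)
    agg <- sample(c("mean", "index", "worst"), 1)
    expect_gte(patient_te(pre, post, aggregation = agg), 0)
  }
})

test_that("TRR is non-increasing and TE non-decreasing in post thresholds", {
  set.seed(11)
  for (i in 1:50) {
    pre <- runif(4, 3, 20)
    post1 <- runif(4, 1, pre)
    post2 <- post1 + runif(4, 0, 3)
    t1 <- patient_trr(pre, post1); t2 <- patient_trr(pre, post2)
    expect_gte(t1, t2)
    expect_lte(patient_te(pre, post1), patient_te(pre, post2))
  }
})

test_that("posts at the reference give TRR = 1 and TE = 0 simultaneously", {
  pre <- c(9, 5, 12); post <- c(2, 2, 2)
  expect_equal(patient_trr(pre, post), 1)
  expect_equal(patient_te(pre, post), 0)
})

test_that("aggregation strategies coincide for single-nerve patients", {
  set.seed(3)
  for (i in 1:20) {
    pre <- runif(1, 2.5, 20); post <- runif(1, 1, pre)
    te <- sapply(c("mean", "index", "worst"),
                 function(a) patient_te(pre, post, aggregation = a))
    pc <- sapply(c("mean", "index", "worst"),
                 function(a) patient_pct_change(pre, post, aggregation = a))
    expect_true(all(te == te[1]))
    expect_true(all(pc == pc[1]))
  }
})

test_that("compute_metrics reproduces the concordant non-improvement patient", {
  m <- compute_metrics(unchanged_patient_cohort())
  expect_equal(m$mean_post_mA, mean(c(9, 6, 5)))
  expect_equal(m$trr, 0)
  expect_equal(m$te, mean(c(9, 6, 5)) - 2)
  expect_equal(m$pain_improvement_frac, 0)
  expect_false(m$mcid)
  expect_false(m$complete_relief)
})

test_that("nerve-level summary counts elevation, improvement and normalization", {
  coh <- make_cohort(list(cbind(c(3, 2), c(2, 2))), 6, 2)
  s <- nerve_level_summary(coh)
  expect_equal(s$n_elevated, 1L)
  expect_equal(s$n_improved, 1L)
  expect_equal(s$n_normalized, 1L)
  expect_equal(s$n_worsened, 0L)

  allsame <- make_cohort(list(cbind(c(5, 7), c(5, 7))), 6, 2)
  expect_equal(nerve_level_summary(allsame)$n_improved, 0L)

  # per-nerve-percentage mean and ratio-of-means are distinct, labeled figures
  coh2 <- make_cohort(list(cbind(c(10, 4), c(5, 1))), 6, 2)
  s2 <- nerve_level_summary(coh2)
  expect_equal(s2$mean_pct_reduction, mean(c(5 / 10, 3 / 4)))
  expect_equal(s2$pooled_pct_reduction, (7 - 3) / 7)
})
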