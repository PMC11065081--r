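test_that("paired t-test matches closed forms and handles degeneracy", {
  p <- as_pairs(c(1, 2, 3), c(1, 2, 3))
  r <- paired_t(p)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  # d = (1,1,1,-1): mean .5, sd 1, n 4 -> t = 1, p from t_3
  r2 <- paired_t(as_pairs(c(1, 1, 1, -1), c(0, 0, 0, 0)))
  expect_equal(r2$t_statistic, 1)
  expect_equal(r2$p_value, 2 * pt(1, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$p_value, 0.391, tolerance = 1e-3)
  # constant nonzero difference: infinite t flagged, not an error
  r3 <- paired_t(as_pairs(c(2, 3, 4), c(1, 2, 3)))
  expect_true(is.infinite(r3$t_statistic))
  expect_true(r3$degenerate)
})

test_that("paired t-test holds its nominal type-I error under the null", {
  rej <- vapply(1:1000, function(r) {
    d <- simulate_paired_metrics(cohort_sim_config(
      30, between_sd = 1, within_sd = 0.5, seed = 20000 + r))
    paired_t(as_pairs(d$session1, d$session2))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)  # 5% +/- 1.5%
})

test_that("ICC(2,1) and its CI reproduce an independent oracle", {
  x1 <- c(10.0, 12.5, 9.8, 14.2, 11.1, 13.3)
  x2 <- c(10.4, 12.1, 10.5, 13.8, 11.9, 12.6)
  p <- as_pairs(x1, x2)
  r <- icc_absolute(p)
  # frozen reference values from an independent two-way ANOVA ICC
  # implementation run on this exact fixture
  expect_equal(r$icc, 0.9278450, tolerance = 1e-6)
  expect_equal(r$ci_low, 0.5721972, tolerance = 1e-6)
  expect_equal(r$ci_high, 0.9896075, tolerance = 1e-6)
  expect_equal(r$icc, icc21_oracle(x1, x2), tolerance = 1e-12)
  expect_equal(icc_absolute(p, form = "ICC(3,1)")$icc, 0.915638,
               tolerance = 1e-5)
  expect_equal(icc_absolute(p, form = "ICC(1,1)")$icc, 0.928323,
               tolerance = 1e-5)
})

test_that("ICC edge cases: perfect agreement, anti-agreement, no variance", {
  p1 <- as_pairs(1:4, 1:4)
  expect_equal(icc_absolute(p1)$icc, 1)
  # session 2 reverses a symmetric set: negative ICC, matches hand ANOVA
  pr <- as_pairs(c(1, 2, 3, 4), c(4, 3, 2, 1))
  r <- icc_absolute(pr)
  expect_lt(r$icc, 0)
  expect_equal(r$icc, icc21_oracle(c(1, 2, 3, 4), c(4, 3, 2, 1)),
               tolerance = 1e-12)
  expect_equal(r$icc, -2)  # MSR = MSC = 0, MSE > 0
  r0 <- icc_absolute(as_pairs(rep(5, 4), rep(5, 4)))
  expect_true(r0$undefined)
  expect_true(is.na(r0$icc))
  expect_error(icc_absolute(as_pairs(1:2, 1:2)), "n >= 3")
})

test_that("ICC recovery and CI coverage across a grid of true values", {
  for (truth in c(0.5, 0.87)) {
    est <- numeric(100); cover <- logical(100)
    for (r in 1:100) {
      cc <- cohort_sim_config(111, between_sd = sqrt(truth),
                              within_sd = sqrt(1 - truth),
                              seed = 31000 + 997 * r)
      d <- simulate_paired_metrics(cc)
      ic <- icc_absolute(as_pairs(d$session1, d$session2))
      est[r] <- ic$icc
      cover[r] <- ic$ci_low <= truth && truth <= ic$ci_high
    }
    expect_lt(abs(mean(est) - truth), 0.03)
    expect_gt(mean(cover), 0.89)
  }
})

test_that("Munro grading follows the published bands", {
  expect_equal(grade_munro(c(0.98, 0.90, 0.87, 0.70, 0.53, 0.50, 0.49)),
               c("excellent", "excellent", "good", "good", "moderate",
                 "moderate", "low"))
  expect_error(grade_munro(NA_real_))
})

test_that("SEM, SEM%, SRD, SRD% match their definitions", {
  expect_equal(sem_measurement(as_pairs(1:4, 1:4)), 0)
  # d = (-1, 0, -2): sd 1, n 3
  expect_equal(sem_measurement(as_pairs(c(0, 1, 0), c(1, 1, 2))),
               1 / sqrt(3))
  # large-n: sem -> sigma_w * sqrt(2) / sqrt(n)
  cc <- cohort_sim_config(20000, between_sd = 3, within_sd = 1, seed = 12)
  d <- simulate_paired_metrics(cc)
  expect_equal(sem_measurement(as_pairs(d$session1, d$session2)),
               sqrt(2) / sqrt(20000), tolerance = 0.03)
  expect_equal(sem_pct(0, 100), 0)
  expect_error(sem_pct(1, 0), "positive")
  expect_equal(srd(0), 0)
  expect_equal(srd(1), sqrt(2))
  expect_equal(srd(1, "conventional"), 1.96 * sqrt(2))
  expect_equal(srd_pct(2, 50), 4)
})

test_that("Bland-Altman bias and limits match their definitions", {
  b0 <- bland_altman(as_pairs(1:4, 1:4))
  expect_equal(c(b0$bias, b0$loa_low, b0$loa_high), c(0, 0, 0))
  # d = (1, -1): bias 0, sd sqrt(2), limits +/- 1.96*sqrt(2)
  b1 <- bland_altman(as_pairs(c(0, 0), c(1, -1)))
  expect_equal(b1$bias, 0)
  expect_equal(b1$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(b1$loa_high, 2.772, tolerance = 1e-3)
  # limit width converges to 2 * 1.96 * sigma_w * sqrt(2)
  cc <- cohort_sim_config(50000, between_sd = 2, within_sd = 1, seed = 13)
  d <- simulate_paired_metrics(cc)
  ba <- bland_altman(as_pairs(d$session1, d$session2))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sqrt(2),
               tolerance = 0.02)
})

test_that("reliability statistics transform correctly under affine maps", {
  set.seed(14)
  x1 <- rnorm(40, 120, 8); x2 <- x1 + rnorm(40, 0, 3)
  r <- reliability_stats(as_pairs(x1, x2))
  a <- 2.5; b <- 40
  rt <- reliability_stats(as_pairs(a * x1 + b, a * x2 + b))
  expect_equal(rt$icc, r$icc, tolerance = 1e-10)        # ICC invariant
  expect_equal(rt$sem, a * r$sem, tolerance = 1e-10)    # sem equivariant
  expect_equal(rt$srd, a * r$srd, tolerance = 1e-10)
  expect_equal(rt$bias, a * r$bias, tolerance = 1e-10)
  expect_equal(rt$loa_high - rt$loa_low, a * (r$loa_high - r$loa_low),
               tolerance = 1e-10)
  # pure scaling leaves the percent measures unchanged
  rs <- reliability_stats(as_pairs(a * x1, a * x2))
  expect_equal(rs$sem_pct, r$sem_pct, tolerance = 1e-10)
  expect_equal(rs$srd_pct, r$srd_pct, tolerance = 1e-10)
  # structural invariants of any emitted row
  expect_equal(r$srd / r$sem, sqrt(2), tolerance = 1e-12)
  expect_lte(r$icc_ci_low, r$icc)
  expect_lte(r$icc, r$icc_ci_high)
  expect_lte(r$loa_low, r$bias)
  expect_lte(r$bias, r$loa_high)
})

test_that("reliability tables partition the cohort under stratification", {
  cc <- cohort_sim_config(40, between_sd = 1, within_sd = 0.5, seed = 15,
                          antihypertensive_fraction = 0.4)
  d <- simulate_paired_metrics(cc)
  metrics <- data.frame(
    participant_id = rep(d$participant_id, 2),
    session = rep(1:2, each = nrow(d)),
    hr = c(d$session1, d$session2) + 60,
    antihypertensive = rep(d$antihypertensive, 2))
  overall <- reliability_table(metrics, metric_cols = "hr")
  strat <- reliability_table(metrics, metric_cols = "hr",
                             stratify_by = "antihypertensive")
  expect_equal(nrow(strat), 2)
  expect_equal(sum(strat$n), overall$n)  # partition: every pair in one stratum
  # a single all-encompassing stratum reproduces the overall row
  metrics$one <- 1
  s1 <- reliability_table(metrics, metric_cols = "hr", stratify_by = "one")
  expect_equal(s1$icc, overall$icc)
  expect_equal(s1$sem, overall$sem)
  # stratum below 3 pairs -> flagged row, not an error
  tiny <- metrics[metrics$participant_id %in% unique(metrics$participant_id)[1:2], ]
  st <- reliability_table(tiny, metric_cols = "hr")
  expect_true(st$undefined)
  expect_true(is.na(st$icc))
})

test_that("stratum-specific true ICCs keep their ordering in estimates", {
  ord_ok <- vapply(1:60, function(r) {
    cc <- cohort_sim_config(
      99, between_sd = 1, within_sd = 1, seed = 40000 + r,
      antihypertensive_fraction = 0.4,
      strata = list("0" = list(between_sd = sqrt(0.93),
                               within_sd = sqrt(0.07)),
                    "1" = list(between_sd = sqrt(0.81),
                               within_sd = sqrt(0.19))))
    d <- simulate_paired_metrics(cc)
    i0 <- icc_absolute(as_pairs(d$session1[d$antihypertensive == 0],
                                d$session2[d$antihypertensive == 0]))$icc
    i1 <- icc_absolute(as_pairs(d$session1[d$antihypertensive == 1],
                                d$session2[d$antihypertensive == 1]))$icc
    i0 > i1
  }, logical(1))
  expect_gte(mean(ord_ok), 0.9)
})
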