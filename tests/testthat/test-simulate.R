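test_that("config validation rejects impossible parameterisations", {
  expect_error(waveform_sim_config(sbp_mean = 80, dbp_mean = 120),
               "sbp_mean")
  expect_error(waveform_sim_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(waveform_sim_config(duration = 1.005, fs = 99.9), "whole")
  expect_error(cohort_sim_config(sessions = 3), "unsupported")
  expect_error(simulate_beat_sequence(quiet_config(duration = 1.2)),
               "degenerate")
})

test_that("all variance sources off gives identical beats at the forced rate", {
  cfg <- quiet_config(duration = 420, hr_mean = 60, seed = 3)
  b <- simulate_beat_sequence(cfg)
  expect_true(all(b$sbp_mmhg == b$sbp_mmhg[1]))
  expect_true(all(b$dbp_mmhg == b$dbp_mmhg[1]))
  expect_true(abs(nrow(b) - 420) <= 1)  # 60 bpm x 7 min
})

test_that("beat truth satisfies its ordering invariants", {
  cfg <- waveform_sim_config(duration = 60, seed = 8)
  b <- simulate_beat_sequence(cfg)
  expect_true(all(diff(b$peak_time_s) > 0))
  expect_true(all(b$dbp_mmhg < b$sbp_mmhg))
  # trough of beat i lies between peaks i and i+1
  n <- nrow(b)
  expect_true(all(b$trough_time_s[-n] > b$peak_time_s[-n]))
  expect_true(all(b$trough_time_s[-n] < b$peak_time_s[-1]))
})

test_that("empirical ARV of iid Gaussian beats matches 2*sigma/sqrt(pi)", {
  cfg <- waveform_sim_config(innovation_sd = 2, ar_coefficient = 0,
                             lf_amplitude = 0, resp_amplitude = 0,
                             hr_sd = 0, seed = 5)
  b <- simulate_beat_sequence(cfg, n_beats = 1e5)
  expect_equal(metric_arv(b$sbp_mmhg), 2 * 2 / sqrt(pi), tolerance = 0.02)
})

test_that("long-run SBP SD converges to the variance-component closed form", {
  cfg <- waveform_sim_config(innovation_sd = 2, ar_coefficient = 0.4,
                             lf_amplitude = 3, resp_amplitude = 1.5,
                             seed = 6)
  b <- simulate_beat_sequence(cfg, n_beats = 2e5)
  expected <- sqrt(2^2 / (1 - 0.4^2) + 3^2 / 2 + 1.5^2 / 2)
  expect_equal(sd(b$sbp_mmhg), expected, tolerance = 0.03)
})

test_that("same seed gives bit-identical beats and waveforms", {
  cfg <- waveform_sim_config(duration = 20, seed = 42)
  b1 <- simulate_beat_sequence(cfg)
  b2 <- simulate_beat_sequence(cfg)
  expect_identical(b1, b2)
  expect_identical(render_waveform(b1, cfg)$samples,
                   render_waveform(b2, cfg)$samples)
  d <- simulate_paired_metrics(cohort_sim_config(10, seed = 9))
  expect_identical(d, simulate_paired_metrics(cohort_sim_config(10, seed = 9)))
})

test_that("rendering reproduces true amplitudes and notch morphology", {
  cw <- clean_waveform(duration = 30, notch_depth = 0)
  s <- cw$waveform$samples
  pk <- cw$beats$peak_time_s
  # notch_depth = 0: single local maximum between consecutive systolic peaks
  locmax <- which(diff(sign(diff(s))) < 0) + 1L
  locmax <- locmax[s[locmax] > 85]  # ignore numeric ripples near the trough
  for (k in seq_len(length(pk) - 1)) {
    inseg <- locmax[locmax / 100 >= pk[k] & locmax / 100 < pk[k + 1]]
    expect_lte(length(inseg), 1)
  }
  # notch_depth = 0.4: at least one secondary maximum per beat interval
  cw4 <- clean_waveform(duration = 30, notch_depth = 0.4)
  s4 <- cw4$waveform$samples
  locmax4 <- which(diff(sign(diff(s4))) < 0) + 1L
  expect_gt(length(locmax4), 2 * (nrow(cw4$beats) - 2))
  # amplitude fidelity: rendered max per beat == sbp, min between == dbp
  b <- cw4$beats
  for (k in seq(2, nrow(b) - 1, by = 7)) {
    i1 <- round(b$peak_time_s[k] * 100); i2 <- round(b$peak_time_s[k + 1] * 100)
    expect_lt(abs(max(s4[i1:i2]) - b$sbp_mmhg[k]), 0.5)
    expect_lt(abs(min(s4[i1:i2]) - b$dbp_mmhg[k]), 0.5)
  }
})

test_that("artifact injection is identity at rate 0 and Poisson otherwise", {
  cw <- clean_waveform(duration = 30)
  out <- inject_artifacts(cw$waveform, cw$config)  # artifact_rate = 0
  expect_identical(out$waveform$samples, cw$waveform$samples)
  expect_identical(nrow(out$intervals), 0L)

  counts <- vapply(1:40, function(sd_) {
    cfg <- waveform_sim_config(duration = 420, artifact_rate = 2,
                               artifact_magnitude = 60, seed = sd_)
    b <- simulate_beat_sequence(cfg)
    nrow(inject_artifacts(render_waveform(b, cfg), cfg)$intervals)
  }, numeric(1))
  lam <- 2 * 420 / 60  # 14 expected events
  expect_true(all(counts >= qpois(0.0005, lam) &
                    counts <= qpois(0.9995, lam)))
  expect_equal(mean(counts), lam, tolerance = 0.15)
})

test_that("metric-level cohort honours its variance structure", {
  # no within-subject noise: sessions identical, estimated ICC = 1
  d0 <- simulate_paired_metrics(
    cohort_sim_config(20, between_sd = 2, within_sd = 0, seed = 2))
  expect_identical(d0$session1, d0$session2)
  expect_equal(icc_absolute(as_pairs(d0$session1, d0$session2))$icc, 1)
  # no between-subject variance: true ICC 0
  dcfg <- cohort_sim_config(30, between_sd = 0, within_sd = 1, seed = 3)
  expect_equal(attr(simulate_paired_metrics(dcfg), "true_icc"), 0)
  # stratum overrides flow through
  dcfg2 <- cohort_sim_config(200, between_sd = 1, within_sd = 1, seed = 4,
                             strata = list("1" = list(within_sd = 0)))
  d2 <- simulate_paired_metrics(dcfg2)
  on_med <- d2$antihypertensive == 1
  expect_identical(d2$session1[on_med], d2$session2[on_med])
  expect_false(all(d2$session1[!on_med] == d2$session2[!on_med]))
})

test_that("ICC estimates recover the simulated truth at n = 111", {
  est <- vapply(1:200, function(r) {
    cc <- cohort_sim_config(111, between_sd = sqrt(0.87),
                            within_sd = sqrt(0.13), seed = 5000 + r)
    d <- simulate_paired_metrics(cc)
    icc_absolute(as_pairs(d$session1, d$session2))$icc
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.87), 0.02)
})

test_that("waveform-level cohort round-trips truth through the pipeline", {
  dir <- withr::local_tempdir()
  wc <- waveform_sim_config(duration = 60, seed = 7, artifact_rate = 0)
  man <- simulate_cohort(cohort_sim_config(3, between_sd = 6, within_sd = 1,
                                           seed = 7), dir, wc)
  expect_equal(nrow(man), 6)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  truth <- read.csv(file.path(dir, "P001_s1_truth.csv"))
  wf <- read_waveform_csv(file.path(dir, "P001_s1.csv"))
  bs <- delineate(wf)
  # generator-truth SD and ARV reproduced within 2% by render -> detect
  expect_equal(metric_sd(bs$sbp_values), sd(truth$sbp_mmhg),
               tolerance = 0.02)
  expect_equal(metric_arv(bs$sbp_values), metric_arv(truth$sbp_mmhg),
               tolerance = 0.02)
})
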