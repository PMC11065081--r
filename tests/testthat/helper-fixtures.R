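# Shared fixtures, all built in code at test time.

# Noise-free generator config: every variance source off.
quiet_config <- function(...) {
  waveform_sim_config(hr_sd = 0, innovation_sd = 0, lf_amplitude = 0,
                      resp_amplitude = 0, ...)
}

# Clean rendered 120/80 waveform of `duration` seconds.
clean_waveform <- function(duration = 30, notch_depth = 0.25, seed = 1) {
  cfg <- quiet_config(duration = duration, sbp_mean = 120, dbp_mean = 80,
                      notch_depth = notch_depth, seed = seed)
  list(config = cfg, beats = simulate_beat_sequence(cfg),
       waveform = render_waveform(simulate_beat_sequence(cfg), cfg))
}

# Minimal hand-built beat_series for unit tests of downstream metrics.
fake_beat_series <- function(peak_times, sbp, dbp = NULL,
                             gap_after = NULL) {
  n <- length(peak_times)
  if (is.null(dbp)) dbp <- rep(NA_real_, n - 1)
  if (is.null(gap_after)) gap_after <- rep(FALSE, n)
  structure(list(
    peak_indices = round(peak_times * 100) + 1L,
    peak_times = peak_times, sbp_values = sbp,
    trough_indices = seq_len(n - 1L),
    trough_times = head(peak_times, -1) + diff(peak_times) * 0.9,
    dbp_values = dbp, gap_after = gap_after, n_beats = n,
    excluded_fraction = 0, accepted = TRUE, fs = 100,
    params = detection_params()), class = "beat_series")
}

# Brute-force two-way ANOVA ICC(2,1) oracle on an n x 2 table, kept
# independent of the package's own decomposition (uses lm/anova).
icc21_oracle <- function(x1, x2) {
  n <- length(x1)
  d <- data.frame(y = c(x1, x2),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- anova(stats::lm(y ~ subj + sess, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}
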