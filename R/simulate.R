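#' Configuration for the synthetic waveform generator
#'
#' Collects every tunable of the beat-sequence and waveform renderer. The
#' per-beat systolic amplitude model is
#' \deqn{SBP_k = \mu_{sbp} + o + A_{lf}\sin(2\pi f_{lf} t_k) +
#'   A_{resp}\sin(2\pi f_{resp} t_k) + e_k}
#' where \eqn{o} is a subject offset and \eqn{e_k} is an AR(1) innovation
#' process with marginal step standard deviation `innovation_sd` and
#' autoregression `ar_coefficient` (white noise at 0). Diastolic amplitudes
#' follow the same model around `dbp_mean` with an independent innovation
#' stream but shared low-frequency and respiratory oscillations. The
#' low-frequency default of 0.1 Hz models Mayer waves; 0.25 Hz models
#' respiratory coupling.
#'
#' @param duration Segment length in seconds (default 420, i.e. the 7-minute
#'   scan window the analysis targets).
#' @param fs Sampling rate, Hz (default 100).
#' @param hr_mean,hr_sd Heart rate mean and beat-to-beat SD, bpm.
#' @param sbp_mean,dbp_mean Baseline systolic/diastolic pressure, mmHg.
#' @param innovation_sd AR(1) innovation SD, mmHg.
#' @param ar_coefficient AR(1) coefficient in [0, 1).
#' @param lf_amplitude,lf_frequency Low-frequency (Mayer-wave) oscillation
#'   amplitude (mmHg) and frequency (Hz, default 0.1).
#' @param resp_amplitude,resp_frequency Respiratory oscillation amplitude
#'   (mmHg) and frequency (Hz, default 0.25).
#' @param notch_depth Dicrotic-notch bump height as a fraction of pulse
#'   pressure, in [0, 1).
#' @param artifact_rate Motion-artifact events per minute.
#' @param artifact_magnitude Artifact excursion height, mmHg.
#' @param seed Integer seed; every random draw of the generator flows from it.
#'
#' @return A list of class `waveform_sim_config`.
#' @export
waveform_sim_config <- function(duration = 420, fs = 100,
                                hr_mean = 60, hr_sd = 2,
                                sbp_mean = 125, dbp_mean = 75,
                                innovation_sd = 2, ar_coefficient = 0.3,
                                lf_amplitude = 3, lf_frequency = 0.1,
                                resp_amplitude = 1.5, resp_frequency = 0.25,
                                notch_depth = 0.25,
                                artifact_rate = 0, artifact_magnitude = 80,
                                seed = 1L) {
  cfg <- list(duration = duration, fs = fs, hr_mean = hr_mean, hr_sd = hr_sd,
              sbp_mean = sbp_mean, dbp_mean = dbp_mean,
              innovation_sd = innovation_sd, ar_coefficient = ar_coefficient,
              lf_amplitude = lf_amplitude, lf_frequency = lf_frequency,
              resp_amplitude = resp_amplitude, resp_frequency = resp_frequency,
              notch_depth = notch_depth, artifact_rate = artifact_rate,
              artifact_magnitude = artifact_magnitude, seed = as.integer(seed))
  n_samp <- cfg$duration * cfg$fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("duration * fs must be a whole number of samples", call. = FALSE)
  if (cfg$sbp_mean <= cfg$dbp_mean)
    stop("sbp_mean must exceed dbp_mean", call. = FALSE)
  amps <- c(cfg$hr_sd, cfg$innovation_sd, cfg$lf_amplitude,
            cfg$resp_amplitude, cfg$artifact_rate)
  if (any(amps < 0)) stop("amplitudes and rates must be >= 0", call. = FALSE)
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
  if (cfg$notch_depth < 0 || cfg$notch_depth >= 1)
    stop("notch_depth must lie in [0, 1)", call. = FALSE)
  class(cfg) <- "waveform_sim_config"
  cfg
}

# Evaluate expr under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

ar1_series <- function(n, sd, ar) {
  if (sd == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))  # stationary start
  if (n > 1) {
    eta <- stats::rnorm(n - 1, 0, sd)
    for (k in 2:n) e[k] <- ar * e[k - 1] + eta[k - 1]
  }
  e
}

#' Simulate a ground-truth beat sequence
#'
#' Draws beat times and per-beat systolic/diastolic amplitudes under the
#' model described in [waveform_sim_config()]. Beat intervals are 60 divided
#' by a per-beat heart rate drawn from N(`hr_mean`, `hr_sd`).
#'
#' @param config A [waveform_sim_config()].
#' @param subject_offset Subject-level shift added to both pressures, mmHg.
#' @param n_beats Optional; override the number of beats instead of filling
#'   `config$duration` (used for long-run convergence checks).
#'
#' @return A data.frame of class `beat_truth` with columns `beat_index`,
#'   `peak_time_s`, `sbp_mmhg`, `trough_time_s`, `dbp_mmhg`. Peak times are
#'   strictly increasing, the trough of beat *i* lies between the peaks of
#'   beats *i* and *i + 1*, and `dbp < sbp` for every beat.
#' @export
simulate_beat_sequence <- function(config, subject_offset = 0, n_beats = NULL) {
  stopifnot(inherits(config, "waveform_sim_config"))
  with_seed(config$seed, {
    if (is.null(n_beats)) {
      # generous draw, then trim to duration
      n_guess <- ceiling(config$duration * config$hr_mean / 60 * 1.5) + 8L
      hr <- pmax(stats::rnorm(n_guess, config$hr_mean, config$hr_sd), 20)
      pt <- 0.5 + cumsum(c(0, 60 / hr[-length(hr)]))
      keep <- pt <= config$duration - 0.3
      pt <- pt[keep]
    } else {
      hr <- pmax(stats::rnorm(n_beats, config$hr_mean, config$hr_sd), 20)
      pt <- 0.5 + cumsum(c(0, 60 / hr[-length(hr)]))
    }
    n <- length(pt)
    if (n < 2)
      stop("degenerate configuration: duration too short for 2 beats",
           call. = FALSE)
    osc <- config$lf_amplitude * sin(2 * pi * config$lf_frequency * pt) +
      config$resp_amplitude * sin(2 * pi * config$resp_frequency * pt)
    sbp <- config$sbp_mean + subject_offset + osc +
      ar1_series(n, config$innovation_sd, config$ar_coefficient)
    dbp <- config$dbp_mean + subject_offset + osc +
      ar1_series(n, config$innovation_sd, config$ar_coefficient)
    dbp <- pmin(dbp, sbp - 10)  # keep pulse pressure physiological
    ibi <- c(diff(pt), if (n > 1) diff(pt)[n - 1] else 1)
    # rendered diastolic minimum sits at 90% of the beat interval
    trough <- pt + 0.9 * ibi
    structure(data.frame(beat_index = seq_len(n), peak_time_s = pt,
                         sbp_mmhg = sbp, trough_time_s = trough,
                         dbp_mmhg = dbp),
              class = c("beat_truth", "data.frame"))
  })
}

#' Render a continuous waveform from a beat sequence
#'
#' Builds a stylized arterial pulse for each beat: a cosine-squared decay
#' from the systolic peak to the diastolic trough at 90% of the beat
#' interval, a Gaussian dicrotic bump of relative height `notch_depth`
#' centred 30% of the interval after the peak, and a smooth rapid upstroke
#' to the next peak. The template is deliberately schematic (no Windkessel
#' dynamics): it exists to exercise peak/trough delineation, including the
#' failure mode in which dicrotic notches are misdetected as systolic peaks
#' when the refractory period is too short.
#'
#' The rendered maximum of each beat equals its true SBP and the minimum
#' between consecutive peaks equals the true DBP, both within 0.5 mmHg.
#'
#' @param beats A `beat_truth` data.frame from [simulate_beat_sequence()].
#' @param config The [waveform_sim_config()] used to generate it.
#' @return A [bp_waveform()] spanning `config$duration` seconds.
#' @export
render_waveform <- function(beats, config) {
  stopifnot(is.data.frame(beats), nrow(beats) >= 2)
  n_samp <- round(config$duration * config$fs)
  t <- (seq_len(n_samp) - 1L) / config$fs
  p <- numeric(n_samp)
  pt <- beats$peak_time_s
  sbp <- beats$sbp_mmhg
  dbp <- beats$dbp_mmhg
  nb <- length(pt)

  pulse <- function(u, sbp_k, dbp_k, sbp_next, depth) {
    # u in [0,1): fraction of the current peak-to-peak interval.
    # Four cosine-smoothed segments: systolic decay to the notch baseline
    # (u < 0.15), dicrotic bump on a flat baseline (0.15-0.45, centred at
    # 0.3 like a real dicrotic notch ~300 ms after the peak), diastolic
    # decay to the trough at u = 0.9, then the rapid upstroke to the next
    # peak. The bump height is depth * (sbp - baseline), so it is a
    # secondary maximum for any depth in (0, 1).
    pp <- sbp_k - dbp_k
    L1 <- dbp_k + 0.40 * pp  # end of early systolic decay
    L2 <- dbp_k + 0.25 * pp  # start of late diastolic runoff
    out <- numeric(length(u))
    s1 <- u < 0.15
    out[s1] <- L1 + (sbp_k - L1) * (1 + cos(pi * u[s1] / 0.15)) / 2
    s2 <- u >= 0.15 & u < 0.45
    w <- (u[s2] - 0.15) / 0.3
    out[s2] <- L1 + (L2 - L1) * w +
      depth * (sbp_k - L2) * (1 - cos(2 * pi * w)) / 2
    s3 <- u >= 0.45 & u < 0.9
    out[s3] <- dbp_k + (L2 - dbp_k) *
      (1 + cos(pi * (u[s3] - 0.45) / 0.45)) / 2
    s4 <- u >= 0.9
    out[s4] <- dbp_k + (sbp_next - dbp_k) *
      (1 - cos(pi * (u[s4] - 0.9) / 0.1)) / 2
    out
  }

  # head: constant diastolic then upstroke into the first peak
  head_idx <- t < pt[1]
  if (any(head_idx)) {
    th <- t[head_idx]
    rise <- th > pt[1] - 0.12
    p[head_idx] <- dbp[1]
    v <- (th[rise] - (pt[1] - 0.12)) / 0.12
    p[head_idx][rise] <- dbp[1] + (sbp[1] - dbp[1]) * (1 - cos(pi * v)) / 2
  }
  for (k in seq_len(nb - 1L)) {
    idx <- which(t >= pt[k] & t < pt[k + 1])
    if (!length(idx)) next
    u <- (t[idx] - pt[k]) / (pt[k + 1] - pt[k])
    p[idx] <- pulse(u, sbp[k], dbp[k], sbp[k + 1], config$notch_depth)
  }
  # tail: decay the last beat with its own interval
  last_ibi <- if (nb > 1) pt[nb] - pt[nb - 1] else 1
  idx <- which(t >= pt[nb])
  if (length(idx)) {
    u <- pmin((t[idx] - pt[nb]) / last_ibi, 0.899)
    p[idx] <- pulse(u, sbp[nb], dbp[nb], sbp[nb], config$notch_depth)
  }
  bp_waveform(p, fs = config$fs, t0 = 0)
}

#' Inject motion artifacts into a waveform
#'
#' Superimposes Poisson-placed trapezoidal excursions (5% ramps) of height
#' `artifact_magnitude` and random duration 0.5-3 s, mimicking transient
#' motion/pressure-loss events in finger-cuff recordings. The spectral
#' content of real motion artifacts is not modelled; this is a schematic
#' surrogate whose ground-truth extents are returned for mask-validation.
#'
#' @param waveform A [bp_waveform()].
#' @param config A [waveform_sim_config()]; uses `artifact_rate` (events per
#'   minute), `artifact_magnitude` and `seed`.
#' @return A list with elements `waveform` (corrupted copy) and `intervals`
#'   (data.frame `start_s`, `end_s` of the injected events; zero rows when
#'   `artifact_rate = 0`, in which case the waveform is returned unchanged).
#' @export
inject_artifacts <- function(waveform, config) {
  stopifnot(inherits(waveform, "bp_waveform"))
  dur <- length(waveform$samples) / waveform$fs
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (config$artifact_rate == 0)
    return(list(waveform = waveform, intervals = empty))
  with_seed(config$seed + 77003L, {
    n_ev <- stats::rpois(1, config$artifact_rate * dur / 60)
    if (n_ev == 0) {
      list(waveform = waveform, intervals = empty)
    } else {
      starts <- sort(stats::runif(n_ev, 0, max(dur - 3, 0.1)))
      durs <- stats::runif(n_ev, 0.5, 3)
      s <- waveform$samples
      t <- waveform_times(waveform) - waveform$t0
      for (i in seq_len(n_ev)) {
        s <- s + config$artifact_magnitude *
          trapezoid_profile(t, starts[i], durs[i])
      }
      list(waveform = bp_waveform(s, fs = waveform$fs, t0 = waveform$t0),
           intervals = data.frame(start_s = starts, end_s = starts + durs))
    }
  })
}

trapezoid_profile <- function(t, start, dur) {
  u <- (t - start) / dur
  w <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  ramp <- 0.05
  w[inside] <- pmin(1, pmin(ui, 1 - ui) / ramp)
  w
}
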