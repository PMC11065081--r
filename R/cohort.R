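#' Configuration for a paired two-session cohort simulation
#'
#' Defines the variance structure of a test-retest cohort: each participant
#' has a latent subject level per metric drawn with SD `between_sd`, and
#' each of the two sessions adds independent noise with SD `within_sd`, so
#' the implied true intraclass correlation is
#' `between_sd^2 / (between_sd^2 + within_sd^2)`. Per-stratum overrides let
#' antihypertensive users carry a different variance structure than
#' non-users.
#'
#' @param n_participants Number of participants (>= 2).
#' @param sessions Number of sessions; only 2 is supported.
#' @param between_sd,within_sd Between-/within-subject SDs (metric units).
#' @param metric_mean Population mean of the metric.
#' @param antihypertensive_fraction Proportion of participants on
#'   antihypertensive medication, in [0, 1].
#' @param strata Optional named list of per-stratum overrides, e.g.
#'   `list("0" = list(between_sd = 1), "1" = list(within_sd = 2))`, keyed by
#'   antihypertensive status.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_participants = 111, sessions = 2,
                              between_sd = 1, within_sd = 0.5,
                              metric_mean = 0,
                              antihypertensive_fraction = 0.35,
                              strata = NULL, seed = 1L) {
  if (sessions != 2)
    stop("unsupported design: only 2 sessions are supported", call. = FALSE)
  stopifnot(n_participants >= 2, between_sd >= 0, within_sd >= 0,
            antihypertensive_fraction >= 0, antihypertensive_fraction <= 1)
  structure(list(n_participants = as.integer(n_participants), sessions = 2L,
                 between_sd = between_sd, within_sd = within_sd,
                 metric_mean = metric_mean,
                 antihypertensive_fraction = antihypertensive_fraction,
                 strata = strata, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

true_icc <- function(between_sd, within_sd) {
  if (between_sd == 0 && within_sd == 0) return(NA_real_)
  between_sd^2 / (between_sd^2 + within_sd^2)
}

#' Simulate metric-level paired measurements
#'
#' Fast metric-level realisation of the two-session variance model of
#' [cohort_sim_config()] (no waveforms): exact variance components, known
#' true ICC, deterministic under the seed.
#'
#' @param config A [cohort_sim_config()].
#' @return A data.frame with columns `participant_id`, `antihypertensive`,
#'   `session1`, `session2`, plus attribute `"true_icc"` (per stratum where
#'   overridden).
#' @export
simulate_paired_metrics <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    med <- stats::rbinom(n, 1, config$antihypertensive_fraction)
    bsd <- rep(config$between_sd, n)
    wsd <- rep(config$within_sd, n)
    if (!is.null(config$strata)) {
      for (lv in names(config$strata)) {
        sel <- med == as.numeric(lv)
        ov <- config$strata[[lv]]
        if (!is.null(ov$between_sd)) bsd[sel] <- ov$between_sd
        if (!is.null(ov$within_sd)) wsd[sel] <- ov$within_sd
      }
    }
    subj <- config$metric_mean + stats::rnorm(n, 0, 1) * bsd
    d <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      antihypertensive = med,
      session1 = subj + stats::rnorm(n, 0, 1) * wsd,
      session2 = subj + stats::rnorm(n, 0, 1) * wsd)
    attr(d, "true_icc") <- true_icc(config$between_sd, config$within_sd)
    d
  })
}

#' Simulate a waveform-level paired cohort on disk
#'
#' Full-pipeline realisation: for each participant, a subject pressure
#' offset is drawn with SD `between_sd` (mmHg), and two 7-minute sessions
#' are generated with [simulate_beat_sequence()] and [render_waveform()]
#' (sessions differ through their innovation draws and oscillation phases,
#' plus a per-session offset with SD `within_sd`). Waveforms, per-session
#' ground-truth beat tables, artifact intervals and a cohort manifest are
#' written as CSV under `dir`.
#'
#' @param config A [cohort_sim_config()].
#' @param dir Output directory (created if needed).
#' @param waveform_config A [waveform_sim_config()] template for the
#'   per-session generator (its `seed` is overridden per session).
#' @return The manifest data.frame (`participant_id`, `session`,
#'   `waveform_path`, `antihypertensive`), invisibly written to
#'   `manifest.csv`; ground truth paths in attributes.
#' @export
simulate_cohort <- function(config, dir,
                            waveform_config = waveform_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_participants
  base <- with_seed(config$seed, {
    list(med = stats::rbinom(n, 1, config$antihypertensive_fraction),
         subj = stats::rnorm(n, 0, config$between_sd),
         sess = matrix(stats::rnorm(2 * n, 0, config$within_sd), n, 2))
  })
  rows <- list()
  for (i in seq_len(n)) {
    for (ss in 1:2) {
      wc <- waveform_config
      wc$seed <- (config$seed * 1009L + i * 211L + ss * 7L) %% 2000000000L
      beats <- simulate_beat_sequence(wc, subject_offset = base$subj[i] +
                                        base$sess[i, ss])
      wf <- render_waveform(beats, wc)
      art <- inject_artifacts(wf, wc)
      pid <- sprintf("P%03d", i)
      wpath <- file.path(dir, sprintf("%s_s%d.csv", pid, ss))
      write_waveform_csv(art$waveform, wpath)
      utils::write.csv(beats, file.path(
        dir, sprintf("%s_s%d_truth.csv", pid, ss)), row.names = FALSE)
      utils::write.csv(art$intervals, file.path(
        dir, sprintf("%s_s%d_artifacts.csv", pid, ss)), row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, session = ss,
        waveform_path = basename(wpath),
        antihypertensive = base$med[i])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
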