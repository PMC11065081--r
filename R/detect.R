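#' Peak-detection and artifact-masking parameters
#'
#' Defaults follow common practice for noninvasive continuous BP traces:
#' systolic peaks must exceed 80 mmHg (`min_height`) and be separated by at
#' least `refractory` milliseconds. The refractory default is 400 ms, long
#' enough to reject dicrotic notches (which arrive roughly 300 ms after the
#' systolic peak) yet shorter than any plausible beat interval (400 ms
#' corresponds to 150 bpm). Some published parameterisations quote a
#' "40 ms" minimum separation; at 100 Hz that equals 4 samples and cannot
#' suppress the dicrotic notch, and is best read as 40 *samples* (400 ms) —
#' both behaviours can be reproduced by setting `refractory` accordingly.
#'
#' Artifact rules replace manual visual inspection: samples outside
#' `artifact_bounds` or with a first difference exceeding `max_abs_slope`
#' mmHg/sample are flagged and dilated to whole beats. A waveform is
#' rejected when more than `max_excluded_fraction` of its samples are
#' flagged.
#'
#' @param min_height Minimum systolic peak height, mmHg.
#' @param refractory Minimum peak separation, milliseconds.
#' @param artifact_bounds Length-2 numeric, plausible pressure range (mmHg).
#' @param max_abs_slope Maximum |sample-to-sample difference|, mmHg
#'   (default 25 at 100 Hz, i.e. 2500 mmHg/s: above peak physiological
#'   systolic upstroke slopes but far below spike discontinuities).
#' @param max_excluded_fraction QC rejection threshold on the flagged
#'   fraction (default 0.10).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_height = 80, refractory = 400,
                             artifact_bounds = c(20, 250),
                             max_abs_slope = 25,
                             max_excluded_fraction = 0.10) {
  stopifnot(min_height > 0, refractory > 0,
            length(artifact_bounds) == 2,
            artifact_bounds[1] < artifact_bounds[2],
            max_abs_slope > 0,
            max_excluded_fraction >= 0, max_excluded_fraction <= 1)
  structure(list(min_height = min_height, refractory = refractory,
                 artifact_bounds = artifact_bounds,
                 max_abs_slope = max_abs_slope,
                 max_excluded_fraction = max_excluded_fraction),
            class = "detection_params")
}

#' Flag artifact samples
#'
#' A sample is flagged when it lies outside `params$artifact_bounds` or when
#' the absolute first difference on either side exceeds `params$max_abs_slope`.
#' Flagged runs are then dilated outward to the nearest flanking local
#' minima of the trace (provisional diastolic troughs, found in a 0.25 s
#' neighbourhood), so whole beats are removed rather than partial pulses.
#'
#' @param waveform A [bp_waveform()].
#' @param params A [detection_params()].
#' @return Logical vector, one element per sample; `TRUE` marks artifact.
#' @export
flag_artifacts <- function(waveform, params = detection_params()) {
  s <- waveform$samples
  n <- length(s)
  lo <- params$artifact_bounds[1]
  hi <- params$artifact_bounds[2]
  mask <- s < lo | s > hi
  d <- abs(diff(s))
  steep <- d > params$max_abs_slope
  mask[c(steep, FALSE)] <- TRUE
  mask[c(FALSE, steep)] <- TRUE
  if (!any(mask) || all(mask)) return(mask)

  w <- max(1L, round(0.25 * waveform$fs))
  is_local_min <- function(i) {
    a <- max(1L, i - w); b <- min(n, i + w)
    s[i] <= min(s[a:b]) + 1e-9
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  for (j in runs) {
    i <- starts[j]
    while (i > 1L && !is_local_min(i)) i <- i - 1L
    k <- ends[j]
    while (k < n && !is_local_min(k)) k <- k + 1L
    mask[i:k] <- TRUE
  }
  mask
}

#' Detect systolic peaks
#'
#' Local maxima at least `min_height` mmHg high are retained greedily in
#' descending amplitude order subject to a pairwise separation of at least
#' `refractory` milliseconds (amplitude ties broken by the earlier index).
#' This reproduces the distance-filter semantics of standard peak pickers
#' and is fully deterministic.
#'
#' @param waveform A [bp_waveform()].
#' @param params A [detection_params()].
#' @param mask Optional logical artifact mask; masked samples cannot be
#'   peaks.
#' @return Integer vector of peak sample indices (sorted increasing).
#' @export
detect_peaks <- function(waveform, params = detection_params(), mask = NULL) {
  s <- waveform$samples
  n <- length(s)
  cand <- which(s[-c(1L, n)] > s[-c(n - 1L, n)] &
                  s[-c(1L, n)] >= s[-c(1L, 2L)]) + 1L
  cand <- cand[s[cand] >= params$min_height]
  if (!is.null(mask)) cand <- cand[!mask[cand]]
  if (!length(cand))
    stop(sprintf(
      "no peaks detected (min_height=%g mmHg, refractory=%g ms)",
      params$min_height, params$refractory), call. = FALSE)
  min_sep <- params$refractory / 1000 * waveform$fs
  ord <- cand[order(-s[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect diastolic troughs
#'
#' For each consecutive pair of systolic peaks, returns the index of the
#' lowest sample strictly between them; ties are broken by the earliest
#' index.
#'
#' @param waveform A [bp_waveform()].
#' @param peaks Integer vector of at least two peak indices.
#' @return Integer vector of length `length(peaks) - 1`.
#' @export
detect_troughs <- function(waveform, peaks) {
  if (length(peaks) < 2)
    stop("insufficient beats: need >= 2 peaks to locate troughs",
         call. = FALSE)
  s <- waveform$samples
  vapply(seq_len(length(peaks) - 1L), function(k) {
    a <- peaks[k] + 1L
    b <- peaks[k + 1L] - 1L
    seg <- s[a:b]
    a + which.min(seg) - 1L
  }, integer(1))
}

#' Delineate beats from a continuous BP waveform
#'
#' Composes [flag_artifacts()], [detect_peaks()] and [detect_troughs()]:
#' artifact samples are masked, peaks and troughs are delineated on each
#' contiguous unmasked span of at least 2 s, and the excluded fraction is
#' compared against the QC threshold. Beats inside masked spans are dropped
#' entirely; boundaries between unmasked spans are recorded (`gap_after`) so
#' that successive-difference statistics never bridge a masked gap.
#'
#' @param waveform A [bp_waveform()].
#' @param params A [detection_params()].
#' @return An object of class `beat_series`: peak/trough sample indices,
#'   times (s) and amplitudes (mmHg), a per-beat `gap_after` flag, the
#'   flagged-sample fraction `excluded_fraction` and the QC verdict
#'   `accepted`. Trough slots between peaks that straddle a masked gap are
#'   `NA`. `accepted = FALSE` is a result, not an error.
#' @export
delineate <- function(waveform, params = detection_params()) {
  mask <- flag_artifacts(waveform, params)
  excluded <- mean(mask)
  n <- length(waveform$samples)
  min_span <- 2 * waveform$fs

  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_ok <- r$values & r$lengths >= min_span
  if (!any(seg_ok))
    stop(sprintf(
      "no peaks detected (min_height=%g mmHg, refractory=%g ms): no unmasked span >= 2 s",
      params$min_height, params$refractory), call. = FALSE)

  peak_idx <- integer(0); trough_idx <- integer(0)
  gap_after <- logical(0); trough_na <- logical(0)
  for (j in which(seg_ok)) {
    sub <- bp_waveform(waveform$samples[starts[j]:ends[j]], fs = waveform$fs,
                       t0 = waveform$t0 + (starts[j] - 1L) / waveform$fs)
    pk <- tryCatch(detect_peaks(sub, params), error = function(e) integer(0))
    if (length(pk) < 1) next
    pk_g <- pk + starts[j] - 1L
    if (length(pk) >= 2) {
      tr_g <- detect_troughs(sub, pk) + starts[j] - 1L
    } else tr_g <- integer(0)
    if (length(peak_idx)) {
      gap_after[length(gap_after)] <- TRUE
      trough_idx <- c(trough_idx, NA_integer_)
      trough_na <- c(trough_na, TRUE)
    }
    peak_idx <- c(peak_idx, pk_g)
    trough_idx <- c(trough_idx, tr_g)
    trough_na <- c(trough_na, rep(FALSE, length(tr_g)))
    gap_after <- c(gap_after, rep(FALSE, length(pk_g)))
  }
  if (!length(peak_idx))
    stop(sprintf(
      "no peaks detected (min_height=%g mmHg, refractory=%g ms)",
      params$min_height, params$refractory), call. = FALSE)

  tms <- waveform$t0 + (peak_idx - 1L) / waveform$fs
  tt <- waveform$t0 + (trough_idx - 1L) / waveform$fs
  structure(list(
    peak_indices = peak_idx,
    peak_times = tms,
    sbp_values = waveform$samples[peak_idx],
    trough_indices = trough_idx,
    trough_times = tt,
    dbp_values = ifelse(is.na(trough_idx), NA_real_,
                        waveform$samples[pmax(trough_idx, 1L)]),
    gap_after = gap_after,
    n_beats = length(peak_idx),
    excluded_fraction = excluded,
    accepted = excluded <= params$max_excluded_fraction,
    fs = waveform$fs,
    params = params), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> %d beats, SBP %.1f +/- %.1f mmHg, DBP %.1f +/- %.1f mmHg\n",
    x$n_beats, mean(x$sbp_values), stats::sd(x$sbp_values),
    mean(x$dbp_values, na.rm = TRUE), stats::sd(x$dbp_values, na.rm = TRUE)))
  cat(sprintf("  excluded fraction %.3f; QC %s\n", x$excluded_fraction,
              if (x$accepted) "accepted" else "REJECTED (>10% excluded)"))
  invisible(x)
}

#' @export
plot.beat_series <- function(x, waveform = NULL, ...) {
  if (!is.null(waveform)) {
    plot(waveform, ...)
    graphics::points(x$peak_times, x$sbp_values, col = "red", pch = 19,
                     cex = 0.6)
    ok <- !is.na(x$trough_times)
    graphics::points(x$trough_times[ok], x$dbp_values[ok], col = "blue",
                     pch = 19, cex = 0.6)
  } else {
    graphics::plot(x$peak_times, x$sbp_values, type = "b", col = "red",
                   xlab = "time (s)", ylab = "mmHg",
                   ylim = range(c(x$sbp_values, x$dbp_values), na.rm = TRUE),
                   ...)
    ok <- !is.na(x$trough_times)
    graphics::lines(x$trough_times[ok], x$dbp_values[ok], type = "b",
                    col = "blue")
  }
  invisible(x)
}

#' Mean heart rate from delineated beats
#'
#' HR is 60 divided by the mean inter-peak interval in seconds; intervals
#' spanning artifact-masked gaps are excluded.
#'
#' @param beats A `beat_series` from [delineate()].
#' @return Heart rate in bpm.
#' @export
compute_hr <- function(beats) {
  if (beats$n_beats < 2)
    stop("insufficient beats: need >= 2 peaks for heart rate", call. = FALSE)
  ibi <- diff(beats$peak_times)
  use <- !beats$gap_after[-beats$n_beats]
  if (!any(use))
    stop("insufficient beats: no usable inter-beat interval", call. = FALSE)
  60 / mean(ibi[use])
}

#' Write beat annotations and a QC sidecar
#'
#' @param beats A `beat_series`.
#' @param path Annotation CSV path (columns `beat_index,peak_time_s,
#'   sbp_mmhg,trough_time_s,dbp_mmhg`); the QC sidecar JSON is written next
#'   to it with extension `.qc.json`.
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  n <- beats$n_beats
  d <- data.frame(beat_index = seq_len(n),
                  peak_time_s = beats$peak_times,
                  sbp_mmhg = beats$sbp_values,
                  trough_time_s = c(beats$trough_times, NA_real_)[seq_len(n)],
                  dbp_mmhg = c(beats$dbp_values, NA_real_)[seq_len(n)])
  utils::write.csv(d, path, row.names = FALSE)
  qc <- list(excluded_fraction = beats$excluded_fraction,
             accepted = beats$accepted, n_beats = n,
             params = unclass(beats$params))
  jsonlite::write_json(qc, sub("\\.csv$", ".qc.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
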