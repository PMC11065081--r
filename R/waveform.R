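#' Continuous blood-pressure waveform
#'
#' Container for a uniformly sampled arterial pressure trace. Pressures are in
#' mmHg, sampled at `fs` Hz starting at time `t0` seconds.
#'
#' @param samples Numeric vector of pressures (mmHg); all values must be finite.
#' @param fs Sampling rate in Hz (default 100, the rate of typical
#'   noninvasive continuous finger-cuff monitors).
#' @param t0 Time of the first sample in seconds.
#'
#' @return An object of class `bp_waveform`: a list with elements `samples`,
#'   `fs` and `t0`.
#' @examples
#' w <- bp_waveform(100 + 20 * sin(2 * pi * seq(0, 10, by = 0.01)), fs = 100)
#' print(w)
#' @export
bp_waveform <- function(samples, fs = 100, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(samples) < 2 * fs)
    stop("waveform must span at least 2 seconds (", 2 * fs, " samples at ",
         fs, " Hz)", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("waveform samples must all be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs, t0 = as.numeric(t0)),
            class = "bp_waveform")
}

#' @export
print.bp_waveform <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<bp_waveform> %d samples @ %g Hz (%.1f s), range %.1f-%.1f mmHg\n",
              length(x$samples), x$fs, dur,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.bp_waveform <- function(x, ..., xlim = NULL) {
  t <- waveform_times(x)
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "pressure (mmHg)", xlim = xlim, ...)
  invisible(x)
}

waveform_times <- function(waveform) {
  waveform$t0 + (seq_along(waveform$samples) - 1L) / waveform$fs
}

#' Read / write waveform CSV files
#'
#' The on-disk dialect is a two-column CSV with header
#' `time_s,pressure_mmhg`, one row per sample, monotone time at `1/fs`
#' spacing.
#'
#' @param path File path.
#' @return `read_waveform_csv()` returns a [bp_waveform()].
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_mmhg") %in% names(d)))
    stop("waveform CSV must have columns time_s,pressure_mmhg: ", path,
         call. = FALSE)
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("waveform time must be strictly increasing: ", path,
                         call. = FALSE)
  fs <- 1 / stats::median(dt)
  bp_waveform(d$pressure_mmhg, fs = round(fs, 6), t0 = d$time_s[1])
}

#' @rdname read_waveform_csv
#' @param waveform A [bp_waveform()].
#' @export
write_waveform_csv <- function(waveform, path) {
  d <- data.frame(time_s = waveform_times(waveform),
                  pressure_mmhg = waveform$samples)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
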