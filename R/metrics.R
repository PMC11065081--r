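#' Extract an ordered beat-amplitude series
#'
#' Returns the systolic peak (or diastolic trough) amplitudes of a
#' delineated beat series in temporal order, together with the positions of
#' artifact-masked gap boundaries so successive-difference metrics can skip
#' across gaps.
#'
#' @param beats A `beat_series` from [delineate()].
#' @param channel `"systolic"` or `"diastolic"`.
#' @return A list with `values` (mmHg) and `gap_after` (logical; `TRUE` at
#'   position *i* means the step from value *i* to *i + 1* bridges a masked
#'   gap and must not be treated as a consecutive beat pair).
#' @export
beat_amplitudes <- function(beats, channel = c("systolic", "diastolic")) {
  channel <- match.arg(channel)
  if (beats$n_beats < 2)
    stop("insufficient beats: need >= 2 beats for amplitude series",
         call. = FALSE)
  if (channel == "systolic") {
    list(values = beats$sbp_values,
         gap_after = beats$gap_after[-beats$n_beats])
  } else {
    ok <- !is.na(beats$dbp_values)
    v <- beats$dbp_values[ok]
    if (length(v) < 2)
      stop("insufficient beats: need >= 2 diastolic troughs", call. = FALSE)
    # a dropped (NA) trough slot splits the diastolic series there
    gap <- logical(length(v) - 1L)
    pos <- cumsum(ok)
    miss <- which(!ok)
    for (m in miss) {
      p <- pos[m]
      if (p >= 1 && p < length(v)) gap[p] <- TRUE
    }
    list(values = v, gap_after = gap)
  }
}

#' Beat-to-beat variability metrics
#'
#' The five metric families of very short-term BPV, computed on an ordered
#' per-beat amplitude series:
#' \describe{
#'   \item{`metric_sd`}{sample standard deviation (n - 1 denominator), mmHg —
#'     a dispersion metric.}
#'   \item{`metric_cv`}{coefficient of variation, `100 * sd / mean`, percent.}
#'   \item{`metric_arv`}{average real variability: the mean absolute
#'     difference between consecutive beats, mmHg — a sequence metric that
#'     is sensitive to temporal order. Pairs spanning an artifact-masked gap
#'     are excluded rather than bridged.}
#'   \item{`metric_delta`}{maximum minus minimum in the window, mmHg — an
#'     instability metric.}
#'   \item{[metric_vim()]}{variability independent of the mean (separate
#'     help page).}
#' }
#'
#' @param series Numeric amplitude vector in temporal order.
#' @param gap_after Logical vector of length `length(series) - 1`; `TRUE`
#'   marks non-consecutive steps to exclude from ARV.
#' @return A single numeric value.
#' @name bpv_metrics
NULL

#' @rdname bpv_metrics
#' @export
metric_sd <- function(series) {
  if (length(series) < 2)
    stop("insufficient beats: need >= 2 values for SD", call. = FALSE)
  stats::sd(series)
}

#' @rdname bpv_metrics
#' @export
metric_cv <- function(series) {
  m <- mean(series)
  if (m <= 0)
    stop("invalid series: mean must be positive for CV", call. = FALSE)
  100 * metric_sd(series) / m
}

#' @rdname bpv_metrics
#' @export
metric_arv <- function(series, gap_after = NULL) {
  n <- length(series)
  if (n < 2)
    stop("insufficient beats: need >= 2 values for ARV", call. = FALSE)
  d <- abs(diff(series))
  if (!is.null(gap_after)) {
    stopifnot(length(gap_after) == n - 1L)
    d <- d[!gap_after]
  }
  if (!length(d))
    stop("insufficient beats: no usable consecutive pairs for ARV",
         call. = FALSE)
  mean(d)
}

#' @rdname bpv_metrics
#' @export
metric_delta <- function(series) {
  if (!length(series)) stop("empty series", call. = FALSE)
  max(series) - min(series)
}

#' Fit the VIM power-law exponent
#'
#' Variability independent of the mean (VIM) rescales each unit's SD by a
#' fitted power of its mean pressure so that the resulting metric is
#' uncorrelated with mean BP across the sample. The exponent `x` comes from
#' the nonlinear least-squares fit \eqn{sd_i = a \cdot mean_i^x} across
#' units (participant-sessions), minimised by Levenberg-Marquardt with
#' starting values `a = median(sd)/median(mean)`, `x = 1`, bounds
#' `x` in [-5, 5] and relative tolerance 1e-8.
#'
#' @param sds Per-unit SD values (nonnegative), one per unit.
#' @param means Per-unit mean pressures (positive, not all equal).
#' @param scope Label recorded in the fit: `"per-session"` or `"pooled"`.
#' @return An object of class `vim_fit` with components `exponent_x`,
#'   `coefficient_a`, `grand_mean_M` (mean of the unit means, the rescaling
#'   base), `converged` and `fit_scope`. Methods: `coef`, `print`,
#'   `predict` (expected SD at new means), `residuals`.
#' @examples
#' m <- seq(90, 160, by = 10)
#' f <- fit_vim_exponent(0.001 * m^1.5, m)
#' coef(f)
#' @export
fit_vim_exponent <- function(sds, means, scope = c("per-session", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(length(sds) == length(means))
  if (length(means) < 3)
    stop("VIM fit requires >= 3 units", call. = FALSE)
  if (any(means <= 0) || any(sds < 0))
    stop("VIM fit requires positive means and nonnegative sds", call. = FALSE)
  if (length(unique(means)) < 2 || stats::sd(means) == 0)
    stop("VIM fit is degenerate: all unit means equal", call. = FALSE)
  d <- data.frame(s = sds, m = means)
  start <- list(a = stats::median(sds) / stats::median(means), x = 1)
  if (start$a <= 0) start$a <- 1e-6
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ a * m^x, data = d, start = start,
                      lower = c(a = 0, x = -5), upper = c(a = Inf, x = 5),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(exponent_x = NA_real_, coefficient_a = NA_real_,
                grand_mean_M = mean(means), converged = FALSE,
                fit_scope = scope, fit = NULL)
  } else {
    cf <- stats::coef(fit)
    res <- list(exponent_x = unname(cf["x"]),
                coefficient_a = unname(cf["a"]),
                grand_mean_M = mean(means), converged = TRUE,
                fit_scope = scope, fit = fit)
  }
  class(res) <- "vim_fit"
  res
}

#' @export
print.vim_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "VIM power-law fit (%s): sd = %.4g * mean^%.4f, grand mean M = %.2f mmHg\n",
      x$fit_scope, x$coefficient_a, x$exponent_x, x$grand_mean_M))
  } else {
    cat("VIM power-law fit: did not converge\n")
  }
  invisible(x)
}

#' @export
coef.vim_fit <- function(object, ...) {
  c(a = object$coefficient_a, x = object$exponent_x)
}

#' @export
predict.vim_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(newdata)) return(stats::fitted(object$fit))
  m <- if (is.list(newdata)) newdata$m else newdata
  object$coefficient_a * m^object$exponent_x
}

#' @export
residuals.vim_fit <- function(object, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  stats::residuals(object$fit)
}

#' Variability independent of the mean
#'
#' `vim = (sd / mean^x) * M^x` where `x` and the grand mean `M` come from a
#' [fit_vim_exponent()] fit across the sample. With `x = 0` VIM reduces to
#' the SD; with `x = 1` it equals `cv * M / 100`. No rescaling beyond the
#' `M^x` multiplier is applied.
#'
#' @param sd Unit SD, mmHg.
#' @param mean Unit mean pressure, mmHg (> 0).
#' @param fit A converged `vim_fit`.
#' @return Unitless (mmHg-scaled) VIM value.
#' @export
metric_vim <- function(sd, mean, fit) {
  stopifnot(inherits(fit, "vim_fit"))
  if (!fit$converged) stop("VIM fit did not converge", call. = FALSE)
  if (any(mean <= 0))
    stop("invalid series: mean must be positive for VIM", call. = FALSE)
  (sd / mean^fit$exponent_x) * fit$grand_mean_M^fit$exponent_x
}

#' Per-session cardiovascular parameters
#'
#' Computes the full row of session-level parameters from a delineated beat
#' series: heart rate, mean SBP/DBP, and the SD, CV, VIM and ARV of both
#' channels plus the SBP max-minus-min (delta).
#'
#' @param beats An accepted `beat_series`.
#' @param vim_fit_sbp,vim_fit_dbp Converged [fit_vim_exponent()] fits for
#'   the systolic and diastolic channels; `NULL` leaves the VIM columns `NA`
#'   (they can be filled in once the cohort-level fit is available).
#' @param participant_id,session Identifiers copied into the row.
#' @return A one-row data.frame with columns `participant_id`, `session`,
#'   `hr`, `sbp_mean`, `sbp_sd`, `sbp_cv`, `sbp_vim`, `sbp_arv`,
#'   `delta_sbp`, `dbp_mean`, `dbp_sd`, `dbp_cv`, `dbp_vim`, `dbp_arv`,
#'   `n_beats`.
#' @export
session_metrics <- function(beats, vim_fit_sbp = NULL, vim_fit_dbp = NULL,
                            participant_id = NA_character_, session = NA) {
  s <- beat_amplitudes(beats, "systolic")
  d <- beat_amplitudes(beats, "diastolic")
  sbp_sd <- metric_sd(s$values)
  dbp_sd <- metric_sd(d$values)
  sbp_mean <- mean(s$values)
  dbp_mean <- mean(d$values)
  data.frame(
    participant_id = participant_id, session = session,
    hr = compute_hr(beats),
    sbp_mean = sbp_mean, sbp_sd = sbp_sd,
    sbp_cv = metric_cv(s$values),
    sbp_vim = if (is.null(vim_fit_sbp)) NA_real_ else
      metric_vim(sbp_sd, sbp_mean, vim_fit_sbp),
    sbp_arv = metric_arv(s$values, s$gap_after),
    delta_sbp = metric_delta(s$values),
    dbp_mean = dbp_mean, dbp_sd = dbp_sd,
    dbp_cv = metric_cv(d$values),
    dbp_vim = if (is.null(vim_fit_dbp)) NA_real_ else
      metric_vim(dbp_sd, dbp_mean, vim_fit_dbp),
    dbp_arv = metric_arv(d$values, d$gap_after),
    n_beats = beats$n_beats)
}

# canonical report row order (Table-style)
metric_columns <- function() {
  c("hr", "sbp_mean", "sbp_sd", "sbp_cv", "sbp_vim", "sbp_arv", "delta_sbp",
    "dbp_mean", "dbp_sd", "dbp_cv", "dbp_vim", "dbp_arv")
}

#' Fill VIM columns of a cohort metrics table
#'
#' Fits the VIM exponent across participants and populates `sbp_vim` /
#' `dbp_vim`. With `scope = "per-session"` the exponent is fitted
#' separately within each session (each session is a sample in its own
#' right); with `"pooled"` one fit uses all participant-sessions.
#'
#' @param metrics A metrics data.frame with at least `session`, `sbp_mean`,
#'   `sbp_sd`, `dbp_mean`, `dbp_sd`.
#' @param scope `"per-session"` (default) or `"pooled"`.
#' @return The table with `sbp_vim` and `dbp_vim` filled; the fits are
#'   attached as attribute `"vim_fits"`.
#' @export
add_vim_metrics <- function(metrics, scope = c("per-session", "pooled")) {
  scope <- match.arg(scope)
  fits <- list()
  fill <- function(df, ch, sc) {
    sd_col <- paste0(ch, "_sd"); mean_col <- paste0(ch, "_mean")
    f <- fit_vim_exponent(df[[sd_col]], df[[mean_col]], scope = sc)
    list(vim = metric_vim(df[[sd_col]], df[[mean_col]], f), fit = f)
  }
  for (ch in c("sbp", "dbp")) {
    vcol <- paste0(ch, "_vim")
    if (scope == "pooled") {
      r <- fill(metrics, ch, "pooled")
      metrics[[vcol]] <- r$vim
      fits[[ch]] <- r$fit
    } else {
      fits[[ch]] <- list()
      for (ss in sort(unique(metrics$session))) {
        rows <- metrics$session == ss
        r <- fill(metrics[rows, ], ch, "per-session")
        metrics[[vcol]][rows] <- r$vim
        fits[[ch]][[as.character(ss)]] <- r$fit
      }
    }
  }
  attr(metrics, "vim_fits") <- fits
  metrics
}
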