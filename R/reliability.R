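#' Build paired test-retest measurements for one metric
#'
#' Reshapes a long cohort metrics table (one row per participant-session)
#' into the per-metric paired vectors used by the reliability statistics.
#' Participants missing either session, or with an `NA` value in either
#' session, are dropped pairwise for that metric.
#'
#' @param metrics Data.frame with columns `participant_id`, `session`
#'   (values 1 and 2) and the metric column.
#' @param metric Name of the metric column.
#' @return A list of class `paired_measurements`: `metric_name`, `x1`,
#'   `x2`, `participant_ids`.
#' @export
paired_measurements <- function(metrics, metric) {
  stopifnot(metric %in% names(metrics))
  s1 <- metrics[metrics$session == 1, c("participant_id", metric)]
  s2 <- metrics[metrics$session == 2, c("participant_id", metric)]
  m <- merge(s1, s2, by = "participant_id", suffixes = c("_1", "_2"))
  v1 <- m[[paste0(metric, "_1")]]
  v2 <- m[[paste0(metric, "_2")]]
  ok <- !is.na(v1) & !is.na(v2)
  structure(list(metric_name = metric, x1 = v1[ok], x2 = v2[ok],
                 participant_ids = m$participant_id[ok]),
            class = "paired_measurements")
}

#' @rdname paired_measurements
#' @param x1,x2 Session-1 and session-2 value vectors of equal length,
#'   already paired by participant.
#' @param metric_name Label for the metric.
#' @export
as_pairs <- function(x1, x2, metric_name = "metric") {
  stopifnot(length(x1) == length(x2))
  structure(list(metric_name = metric_name, x1 = as.numeric(x1),
                 x2 = as.numeric(x2),
                 participant_ids = seq_along(x1)),
            class = "paired_measurements")
}

#' Paired t-test for session means
#'
#' Two-sided paired t-test of session 1 against session 2,
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x1 - x2` and `n - 1` degrees
#' of freedom. When every difference is zero the test is degenerate and the
#' conventional `t = 0, p = 1` is returned; a nonzero mean difference with
#' zero variance yields an infinite t with `p = 0` and a flag.
#'
#' @param pairs A `paired_measurements` object (or use `x1`, `x2`).
#' @return List with `t_statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_t <- function(pairs) {
  x1 <- pairs$x1; x2 <- pairs$x2
  n <- length(x1)
  if (n < 2) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- x1 - x2
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t_statistic = 0, p_value = 1, df = n - 1,
                  degenerate = TRUE))
    return(list(t_statistic = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x1, x2, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

icc_anova <- function(x1, x2) {
  n <- length(x1); k <- 2
  Y <- cbind(x1, x2)
  gm <- mean(Y)
  rm_ <- rowMeans(Y); cm <- colMeans(Y)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((Y - gm)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       msw = (sst - ssr) / (n * (k - 1)))
}

#' Intraclass correlation for test-retest agreement
#'
#' Default is ICC(2,1): the two-way random-effects, absolute-agreement,
#' single-measurement coefficient
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + MS_E + \frac{2}{n}(MS_C - MS_E)}}
#' from the two-way ANOVA decomposition of the n-by-2 session table, the
#' standard choice for test-retest reliability with a fixed device. The 95%
#' confidence interval uses the F-based method of McGraw & Wong.
#' Consistency ICC(3,1) and one-way ICC(1,1) are available via `form`.
#'
#' @param pairs A `paired_measurements` object with n >= 3.
#' @param form `"ICC(2,1)"` (default), `"ICC(3,1)"` or `"ICC(1,1)"`.
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `form`, `n`, and
#'   `undefined` (`TRUE` when total variance is zero and the coefficient is
#'   undefined; the estimates are then `NA`).
#' @export
icc_absolute <- function(pairs, form = c("ICC(2,1)", "ICC(3,1)", "ICC(1,1)"),
                         conf = 0.95) {
  form <- match.arg(form)
  x1 <- pairs$x1; x2 <- pairs$x2
  n <- length(x1)
  if (n < 3) stop("ICC needs n >= 3 pairs", call. = FALSE)
  if (stats::var(c(x1, x2)) == 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                form = form, n = n, undefined = TRUE))
  a_ <- icc_anova(x1, x2)
  k <- a_$k
  alpha <- 1 - conf
  q <- function(p, d1, d2) stats::qf(p, d1, d2)
  if (form == "ICC(2,1)") {
    icc <- (a_$msr - a_$mse) /
      (a_$msr + (k - 1) * a_$mse + (k / n) * (a_$msc - a_$mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * a_$msc + b * a_$mse)^2 /
      ((a * a_$msc)^2 / (k - 1) + (b * a_$mse)^2 / ((n - 1) * (k - 1)))
    fl <- q(1 - alpha / 2, n - 1, v)
    fu <- q(1 - alpha / 2, v, n - 1)
    lo <- n * (a_$msr - fl * a_$mse) /
      (fl * (k * a_$msc + (k * n - k - n) * a_$mse) + n * a_$msr)
    hi <- n * (fu * a_$msr - a_$mse) /
      (k * a_$msc + (k * n - k - n) * a_$mse + n * fu * a_$msr)
  } else if (form == "ICC(3,1)") {
    icc <- (a_$msr - a_$mse) / (a_$msr + (k - 1) * a_$mse)
    f0 <- a_$msr / a_$mse
    fl <- f0 / q(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f0 * q(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    msb <- a_$msr; msw <- a_$msw
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    f0 <- msb / msw
    fl <- f0 / q(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f0 * q(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  list(icc = icc, ci_low = lo, ci_high = hi, form = form, n = n,
       undefined = FALSE)
}

#' Grade an ICC by Munro's criteria
#'
#' `>= .90` excellent; `.70-.89` good; `.50-.69` moderate; below `.50` low.
#'
#' @param icc A finite ICC estimate (vectorised).
#' @return Character vector of grades.
#' @export
grade_munro <- function(icc) {
  stopifnot(all(is.finite(icc)))
  cut(icc, breaks = c(-Inf, 0.5, 0.7, 0.9, Inf), right = FALSE,
      labels = c("low", "moderate", "good", "excellent")) |> as.character()
}

#' Absolute reliability: SEM, SEM%, SRD, SRD%
#'
#' The standard error of measurement is computed as the sample SD of the
#' paired differences divided by the square root of the number of pairs,
#' `sem = sd(d) / sqrt(n)`. SEM% expresses it relative to the grand mean of
#' both sessions, `100 * sem / grand_mean`. The smallest real difference is
#' `srd = sem * sqrt(2)` by default (`srd_factor = "sqrt2"`); the
#' conventional 95% version `1.96 * sqrt(2) * sem` is available with
#' `srd_factor = "conventional"`. SRD% uses the unrounded SRD over the same
#' grand mean.
#'
#' @param pairs A `paired_measurements` object.
#' @param sem,grand_mean,srd Scalars, for the arithmetic helpers.
#' @param srd_factor `"sqrt2"` (default) or `"conventional"`.
#' @return Numeric scalars.
#' @name absolute_reliability
NULL

#' @rdname absolute_reliability
#' @export
sem_measurement <- function(pairs) {
  n <- length(pairs$x1)
  if (n < 2) stop("SEM needs n >= 2", call. = FALSE)
  stats::sd(pairs$x1 - pairs$x2) / sqrt(n)
}

#' @rdname absolute_reliability
#' @export
sem_pct <- function(sem, grand_mean) {
  if (grand_mean <= 0)
    stop("SEM%% needs a positive grand mean", call. = FALSE)
  100 * sem / grand_mean
}

#' @rdname absolute_reliability
#' @export
srd <- function(sem, srd_factor = c("sqrt2", "conventional")) {
  srd_factor <- match.arg(srd_factor)
  stopifnot(sem >= 0)
  sem * sqrt(2) * if (srd_factor == "conventional") 1.96 else 1
}

#' @rdname absolute_reliability
#' @export
srd_pct <- function(srd, grand_mean) {
  if (grand_mean <= 0)
    stop("SRD%% needs a positive grand mean", call. = FALSE)
  100 * srd / grand_mean
}

#' Bland-Altman agreement
#'
#' Bias is the mean paired difference (`x2 - x1`, retest minus test); the
#' 95% limits of agreement are `bias +/- 1.96 * sd(d)`.
#'
#' @param pairs A `paired_measurements` object.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(pairs) {
  n <- length(pairs$x1)
  if (n < 2) stop("Bland-Altman needs n >= 2", call. = FALSE)
  d <- pairs$x2 - pairs$x1
  b <- mean(d); s <- stats::sd(d)
  list(bias = b, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s,
       sd_diff = s)
}

#' Full reliability summary for one metric
#'
#' @param pairs A `paired_measurements` object (n >= 3 for the ICC).
#' @param icc_form Passed to [icc_absolute()].
#' @param srd_factor Passed to [srd()].
#' @return One-row data.frame with session means/SDs, paired-t, ICC + CI +
#'   Munro grade, SEM, SEM%, SRD, SRD%, Pearson r and Bland-Altman summary.
#' @export
reliability_stats <- function(pairs, icc_form = "ICC(2,1)",
                              srd_factor = "sqrt2") {
  n <- length(pairs$x1)
  if (n < 3) {
    out <- data.frame(metric = pairs$metric_name, n = n)
    out[c("mean1", "mean2", "sd1", "sd2", "t_statistic", "p_value", "icc",
          "icc_ci_low", "icc_ci_high", "sem", "sem_pct", "srd", "srd_pct",
          "pearson_r", "bias", "loa_low", "loa_high")] <- NA_real_
    out$grade <- NA_character_
    out$undefined <- TRUE
    return(out)
  }
  tt <- paired_t(pairs)
  ic <- icc_absolute(pairs, form = icc_form)
  se <- sem_measurement(pairs)
  gm <- (mean(pairs$x1) + mean(pairs$x2)) / 2
  sr <- srd(se, srd_factor)
  ba <- bland_altman(pairs)
  r <- if (stats::sd(pairs$x1) == 0 || stats::sd(pairs$x2) == 0) NA_real_
       else stats::cor(pairs$x1, pairs$x2)
  data.frame(
    metric = pairs$metric_name, n = n,
    mean1 = mean(pairs$x1), mean2 = mean(pairs$x2),
    sd1 = stats::sd(pairs$x1), sd2 = stats::sd(pairs$x2),
    t_statistic = tt$t_statistic, p_value = tt$p_value,
    icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
    grade = if (ic$undefined) NA_character_ else grade_munro(ic$icc),
    sem = se,
    sem_pct = if (gm > 0) sem_pct(se, gm) else NA_real_,
    srd = sr,
    srd_pct = if (gm > 0) srd_pct(sr, gm) else NA_real_,
    pearson_r = r,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    undefined = ic$undefined)
}

#' Test-retest reliability table for a cohort
#'
#' Computes one reliability row per metric, in the canonical report order
#' (HR, mean SBP, SBP SD/CV/VIM/ARV, delta SBP, mean DBP, DBP SD/CV/VIM/ARV),
#' optionally stratified (e.g. by antihypertensive use, coded 0/1 in an
#' `antihypertensive` column). Pairs are formed per metric with pairwise
#' dropping of incomplete participants; strata below 3 complete pairs yield
#' a flagged row with `NA` statistics.
#'
#' @param metrics Long cohort metrics table (participant_id, session,
#'   metric columns, optional stratification column).
#' @param metric_cols Metric columns to summarise (default all present
#'   canonical columns).
#' @param stratify_by Optional column name; one set of rows per level.
#' @param icc_form,srd_factor Passed through to [reliability_stats()].
#' @return A data.frame of class `bpv_reliability` (one row per metric, and
#'   per stratum when stratified; column `stratum` gives the level, or
#'   `"all"`).
#' @export
reliability_table <- function(metrics, metric_cols = NULL,
                              stratify_by = NULL,
                              icc_form = "ICC(2,1)", srd_factor = "sqrt2") {
  if (is.null(metric_cols))
    metric_cols <- intersect(metric_columns(), names(metrics))
  groups <- list(all = metrics)
  if (!is.null(stratify_by)) {
    stopifnot(stratify_by %in% names(metrics))
    lv <- sort(unique(metrics[[stratify_by]]))
    lv <- lv[!is.na(lv)]
    groups <- lapply(lv, function(l) metrics[
      !is.na(metrics[[stratify_by]]) & metrics[[stratify_by]] == l, ])
    names(groups) <- paste0(stratify_by, "=", lv)
  }
  rows <- list()
  for (g in names(groups)) {
    for (mc in metric_cols) {
      p <- paired_measurements(groups[[g]], mc)
      row <- reliability_stats(p, icc_form = icc_form,
                               srd_factor = srd_factor)
      row$stratum <- g
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "icc_form") <- icc_form
  attr(out, "srd_factor") <- srd_factor
  class(out) <- c("bpv_reliability", "data.frame")
  out
}

#' @export
print.bpv_reliability <- function(x, digits = 2, ...) {
  cat(sprintf("Test-retest reliability (%s, SRD factor %s)\n",
              attr(x, "icc_form"), attr(x, "srd_factor")))
  d <- data.frame(
    stratum = x$stratum, metric = x$metric, n = x$n,
    icc = sprintf(paste0("%.", digits, "f (%.", digits, "f-%.",
                         digits, "f)"),
                  x$icc, x$icc_ci_low, x$icc_ci_high),
    grade = x$grade,
    sem = round(x$sem, digits), sem_pct = round(x$sem_pct, digits),
    srd = round(x$srd, digits), srd_pct = round(x$srd_pct, digits),
    p = round(x$p_value, digits))
  print(d, row.names = FALSE)
  invisible(x)
}

#' @export
summary.bpv_reliability <- function(object, ...) {
  cat("Munro grading summary:\n")
  print(table(object$stratum, factor(
    object$grade, levels = c("excellent", "good", "moderate", "low"))))
  invisible(object)
}

#' Agreement plots for one metric
#'
#' Draws the standard test-retest panel for a single metric: paired
#' session distributions, scatter with the identity line and Pearson r, and
#' a Bland-Altman plot with bias and 95% limits of agreement.
#'
#' @param x A `paired_measurements` object.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.paired_measurements <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::boxplot(list(session1 = x$x1, session2 = x$x2),
                    main = x$metric_name, ylab = x$metric_name)
  rng <- range(c(x$x1, x$x2))
  graphics::plot(x$x1, x$x2, xlim = rng, ylim = rng,
                 xlab = "session 1", ylab = "session 2",
                 main = sprintf("r = %.2f", stats::cor(x$x1, x$x2)), ...)
  graphics::abline(0, 1, lty = 2)
  ba <- bland_altman(x)
  avg <- (x$x1 + x$x2) / 2
  graphics::plot(avg, x$x2 - x$x1, xlab = "mean of sessions",
                 ylab = "difference (s2 - s1)", main = "Bland-Altman", ...)
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high), lty = c(1, 2, 2))
  invisible(x)
}
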