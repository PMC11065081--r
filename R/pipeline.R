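#' Pipeline run configuration
#'
#' @param input_manifest Path to a cohort `manifest.csv`
#'   (`participant_id,session,waveform_path,antihypertensive`); waveform
#'   paths are resolved relative to the manifest directory.
#' @param detection A [detection_params()].
#' @param vim_fit_scope `"per-session"` or `"pooled"` VIM exponent fit.
#' @param icc_form `"ICC(2,1)"`, `"ICC(3,1)"` or `"ICC(1,1)"`.
#' @param srd_factor `"sqrt2"` or `"conventional"`.
#' @param window Analysis window in seconds (default 420 = 7 minutes);
#'   longer sessions are truncated to the first `window` seconds, shorter
#'   ones analysed whole with a warning.
#' @param output_dir Directory for report files.
#' @param max_reject_fraction Abort the run when more than this fraction of
#'   sessions fails waveform QC (default 0.5).
#' @param seed Integer seed recorded in the run metadata.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_manifest, detection = detection_params(),
                       vim_fit_scope = "per-session",
                       icc_form = "ICC(2,1)", srd_factor = "sqrt2",
                       window = 420, output_dir = tempfile("bpv_run_"),
                       max_reject_fraction = 0.5, seed = 1L) {
  stopifnot(window > 0)
  structure(list(input_manifest = input_manifest, detection = detection,
                 vim_fit_scope = vim_fit_scope, icc_form = icc_form,
                 srd_factor = srd_factor, window = window,
                 output_dir = output_dir,
                 max_reject_fraction = max_reject_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full BPV reliability pipeline
#'
#' Ingests a cohort manifest of paired continuous BP waveforms, delineates
#' beats with artifact QC, computes the per-session cardiovascular
#' parameters and BPV metrics, and emits the three report tables: session
#' summary with paired-t comparisons, overall test-retest reliability, and
#' reliability stratified by antihypertensive use. All outputs are written
#' to `config$output_dir` as CSV plus a run-metadata JSON; identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return An object of class `bpv_run`: list with `metrics`, `qc`,
#'   `summary_table`, `reliability`, `reliability_stratified`, `config`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- utils::read.csv(config$input_manifest,
                              colClasses = c(participant_id = "character"))
  need <- c("participant_id", "session", "waveform_path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns participant_id,session,waveform_path",
         call. = FALSE)
  root <- dirname(config$input_manifest)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  qc <- list(); met <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- row$waveform_path
    if (!file.exists(path)) path <- file.path(root, row$waveform_path)
    if (!file.exists(path))
      stop("unreadable waveform file: ", row$waveform_path, call. = FALSE)
    wf <- read_waveform_csv(path)
    n_keep <- round(config$window * wf$fs)
    if (length(wf$samples) > n_keep) {
      wf <- bp_waveform(wf$samples[seq_len(n_keep)], wf$fs, wf$t0)
    } else if (length(wf$samples) < n_keep) {
      warning(sprintf("%s session %d: only %.0f s available (< %g s window)",
                      row$participant_id, row$session,
                      length(wf$samples) / wf$fs, config$window),
              call. = FALSE)
    }
    beats <- tryCatch(delineate(wf, config$detection), error = identity)
    failed <- inherits(beats, "error")
    rejected <- failed || !beats$accepted
    qc[[i]] <- data.frame(
      participant_id = row$participant_id, session = row$session,
      excluded_fraction = if (failed) NA_real_ else beats$excluded_fraction,
      n_beats = if (failed) 0L else beats$n_beats,
      accepted = !rejected,
      note = if (failed) conditionMessage(beats) else "")
    if (!rejected)
      met[[length(met) + 1L]] <- cbind(
        session_metrics(beats, participant_id = row$participant_id,
                        session = row$session),
        antihypertensive = if ("antihypertensive" %in% names(row))
          row$antihypertensive else NA)
  }
  qc <- do.call(rbind, qc)
  n_rej <- sum(!qc$accepted)
  if (n_rej > config$max_reject_fraction * nrow(qc))
    stop(sprintf(
      "run aborted: %d of %d sessions rejected by QC (limit %.0f%%)",
      n_rej, nrow(qc), 100 * config$max_reject_fraction), call. = FALSE)
  metrics <- do.call(rbind, met)

  # keep only participants with both sessions accepted
  tab <- table(metrics$participant_id)
  incomplete <- names(tab)[tab < 2]
  if (length(incomplete))
    message("dropping participants with a missing session: ",
            paste(incomplete, collapse = ", "))
  metrics <- metrics[!metrics$participant_id %in% incomplete, ]
  metrics <- add_vim_metrics(metrics, scope = config$vim_fit_scope)

  cols <- intersect(metric_columns(), names(metrics))
  summary_rows <- lapply(cols, function(mc) {
    p <- paired_measurements(metrics, mc)
    tt <- paired_t(p)
    data.frame(metric = mc, n = length(p$x1),
               mean1 = mean(p$x1), sd1 = stats::sd(p$x1),
               mean2 = mean(p$x2), sd2 = stats::sd(p$x2),
               p_value = tt$p_value)
  })
  summary_table <- do.call(rbind, summary_rows)
  rel <- reliability_table(metrics, icc_form = config$icc_form,
                           srd_factor = config$srd_factor)
  rel_strat <- if ("antihypertensive" %in% names(metrics) &&
                   !all(is.na(metrics$antihypertensive)))
    reliability_table(metrics, stratify_by = "antihypertensive",
                      icc_form = config$icc_form,
                      srd_factor = config$srd_factor) else NULL

  out <- config$output_dir
  wr <- function(d, f) utils::write.csv(
    round_df(d), file.path(out, f), row.names = FALSE)
  wr(qc, "qc_summary.csv")
  wr(metrics, "session_metrics.csv")
  wr(summary_table, "session_summary.csv")
  wr(as.data.frame(rel), "reliability_overall.csv")
  if (!is.null(rel_strat))
    wr(as.data.frame(rel_strat), "reliability_stratified.csv")
  jsonlite::write_json(
    list(seed = config$seed, window = config$window,
         icc_form = config$icc_form, srd_factor = config$srd_factor,
         vim_fit_scope = config$vim_fit_scope,
         detection = unclass(config$detection),
         n_sessions = nrow(qc), n_rejected = n_rej,
         version = as.character(utils::packageVersion("beatvar"))),
    file.path(out, "run_metadata.json"), auto_unbox = TRUE, digits = NA)

  structure(list(metrics = metrics, qc = qc, summary_table = summary_table,
                 reliability = rel, reliability_stratified = rel_strat,
                 config = config, output_dir = out),
            class = "bpv_run")
}

# report-table rounding: 2 decimals, round-half-even, serialization only
round_df <- function(d, digits = 2) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits = digits)
  d
}

#' @export
print.bpv_run <- function(x, ...) {
  cat(sprintf("<bpv_run> %d sessions (%d rejected by QC), %d participants\n",
              nrow(x$qc), sum(!x$qc$accepted),
              length(unique(x$metrics$participant_id))))
  print(x$reliability)
  invisible(x)
}
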