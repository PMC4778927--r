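# File I/O: settings, session records and reports as JSON; event logs and
# traces as CSV. All times ms, rates bpm, amplitudes mV.

#' Write pacemaker settings to a JSON file
#' @param settings A `pacemaker_settings` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_settings <- function(settings, file) {
  jsonlite::write_json(unclass(settings), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read pacemaker settings from a JSON file
#'
#' Unknown keys are rejected; values pass through [set_parameter()] so the
#' device constraints hold on the result.
#'
#' @param file JSON path written by [write_settings()] (or hand-edited).
#' @return A `pacemaker_settings` object.
#' @export
read_settings <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  s <- default_settings()
  known <- names(s)
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("unknown settings key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  # apply rate/refractory context first so the AV-delay clamp sees it
  for (nm in intersect(c("mode", "mtr_bpm", "pvarp_ms", "basic_rate_bpm",
                         "a_sense_mV", "v_sense_mV", "a_stim_V", "v_stim_V",
                         "crosstalk_mV", "av_delay_ms", "power_on"),
                       names(raw)))
    s <- set_parameter(s, nm, raw[[nm]])
  s
}

#' Write a session record to JSON
#' @param session A `session_record`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_session <- function(session, file) {
  jsonlite::write_json(unclass(session), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a session record from JSON
#' @param file Path written by [write_session()].
#' @return A `session_record` (validated).
#' @export
read_session <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  session_record(
    jet_rate_bpm = as.numeric(raw$jet_rate_bpm),
    actions = lapply(raw$actions, function(a) {
      a$step <- as.character(a$step)
      a
    }),
    signal_amplitude_mV = as.numeric(raw$signal_amplitude_mV %||% 5))
}

#' Write a session report to JSON
#' @param report A `session_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  out <- list(
    jet_rate_bpm = report$jet_rate_bpm,
    total = report$total,
    scores = report$scores,
    behavior = if (!is.null(report$behavior)) list(
      label = report$behavior$label,
      evidence = report$behavior$evidence) else NULL,
    final_settings = unclass(report$final_settings))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(file)
}

#' Write an event log to CSV
#' @param event_log An `avt_event_log`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_event_log_csv <- function(event_log, file) {
  write.csv(as.data.frame(event_log), file, row.names = FALSE)
  invisible(file)
}

#' Read an event log from CSV
#' @param file Path written by [write_event_log_csv()].
#' @return An `avt_event_log` data frame.
#' @export
read_event_log_csv <- function(file) {
  log <- read.csv(file, stringsAsFactors = FALSE)
  log$time_ms <- as.numeric(log$time_ms)
  log$amplitude_mV <- as.numeric(log$amplitude_mV)
  structure(log, class = c("avt_event_log", "data.frame"))
}

#' Write a trace (and its annotations) to CSV
#'
#' The trace goes to `file` as `time_ms` plus one column per channel; if
#' the trace carries annotations they go to a sibling file with suffix
#' `_annotations.csv` as `time_ms,label`.
#'
#' @param trace A `waveform_trace`.
#' @param file Output path (`.csv`).
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  write.csv(as.data.frame(trace), file, row.names = FALSE)
  if (nrow(trace$annotations)) {
    ann_file <- sub("\\.csv$", "_annotations.csv", file)
    write.csv(trace$annotations, ann_file, row.names = FALSE)
  }
  invisible(file)
}
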