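# Wiring rig: lead-swap plan, dummy load, closed-loop simulation.

#' Connect the temporary pacing wires
#'
#' Records which device input each wire pair goes to and in which order the
#' pairs were connected. The AVT-correct hookup is deliberately swapped:
#' ventricular wires to the device's atrial input, atrial wires to the
#' ventricular input, with a 2000 Ohm dummy load on the atrial-wire path so
#' the device's wire-disconnection alarm stays quiet.
#'
#' @param ventricular_wires_to Device input the ventricular wire pair is
#'   plugged into: `"atrial"` (AVT-correct) or `"ventricular"`.
#' @param atrial_wires_to Device input for the atrial wire pair.
#' @param connection_order `"ventricular_first"` (safety-correct) or
#'   `"atrial_first"`.
#' @param dummy_load_ohm Resistance on the atrial-wire path (default 2000);
#'   `0` or `NA` means no load.
#' @return A `wiring_plan` with fields as above plus `avt_correct` and
#'   `disconnection_alarm`.
#' @export
connect_wires <- function(ventricular_wires_to = "atrial",
                          atrial_wires_to = "ventricular",
                          connection_order = "ventricular_first",
                          dummy_load_ohm = 2000) {
  inputs <- c("atrial", "ventricular")
  if (!ventricular_wires_to %in% inputs || !atrial_wires_to %in% inputs)
    stop("wire assignments must be 'atrial' or 'ventricular'", call. = FALSE)
  if (ventricular_wires_to == atrial_wires_to)
    stop("both wire pairs assigned to the same device input", call. = FALSE)
  if (!connection_order %in% c("ventricular_first", "atrial_first"))
    stop("connection_order must be 'ventricular_first' or 'atrial_first'",
         call. = FALSE)
  has_load <- !is.null(dummy_load_ohm) && !is.na(dummy_load_ohm) &&
    dummy_load_ohm > 0
  structure(list(
    ventricular_wires_to = ventricular_wires_to,
    atrial_wires_to = atrial_wires_to,
    connection_order = connection_order,
    dummy_load_ohm = if (has_load) dummy_load_ohm else 0,
    avt_correct = ventricular_wires_to == "atrial" &&
      atrial_wires_to == "ventricular",
    disconnection_alarm = !has_load
  ), class = "wiring_plan")
}

#' @export
print.wiring_plan <- function(x, ...) {
  cat(sprintf("<wiring_plan> V wires -> %s input, A wires -> %s input (%s)\n",
              x$ventricular_wires_to, x$atrial_wires_to, x$connection_order))
  cat(sprintf("  AVT-correct: %s | dummy load %g Ohm | disconnection alarm: %s\n",
              x$avt_correct, x$dummy_load_ohm, x$disconnection_alarm))
  invisible(x)
}

#' Run the closed-loop AVT simulation
#'
#' Generates the JET trigger train, routes it to the device input given by
#' the wiring plan, and advances the pacemaker timing cycle over the full
#' duration. Deterministic for identical inputs (including phase); optional
#' seeded Gaussian rate jitter is available for robustness experiments.
#'
#' @param settings A `pacemaker_settings` object.
#' @param wiring A `wiring_plan` (default: AVT-correct hookup).
#' @param jet_rate_bpm JET source rate, one of [JET_RATES].
#' @param duration_s Simulation length in seconds.
#' @param amplitude_mV Intrinsic signal amplitude at the device input
#'   (default 5).
#' @param phase_ms Time of the first JET beat (default 0).
#' @param jitter_sd_bpm Standard deviation of per-beat rate jitter, bpm
#'   (default 0 = regular rhythm).
#' @param seed Seed used when `jitter_sd_bpm > 0`.
#' @param include_trace If `TRUE`, also synthesize the monitor trace
#'   (derived leads, low-pass, pacing-spike annotations) and attach it as
#'   the `"trace"` attribute of the returned log.
#' @return An `avt_event_log` (see [pm_run()]). If the device is off, an
#'   empty log whose `"note"` attribute is `"device_off"`.
#' @export
run_simulation <- function(settings, wiring = connect_wires(), jet_rate_bpm,
                           duration_s, amplitude_mV = 5, phase_ms = 0,
                           jitter_sd_bpm = 0, seed = NULL,
                           include_trace = FALSE) {
  validate_rate(jet_rate_bpm)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (!isTRUE(settings$power_on)) {
    log <- data.frame(time_ms = numeric(0), channel = character(0),
                      kind = character(0), detail = character(0),
                      amplitude_mV = numeric(0))
    return(structure(log, class = c("avt_event_log", "data.frame"),
                     settings = settings, note = "device_off"))
  }

  if (jitter_sd_bpm > 0) {
    if (!is.null(seed)) set.seed(seed)
    times <- c()
    t <- phase_ms
    while (t < duration_s * 1000) {
      times <- c(times, t)
      rate <- max(30, jet_rate_bpm + rnorm(1L, 0, jitter_sd_bpm))
      t <- t + 60000 / rate
    }
    train <- structure(list(event_times_ms = times,
                            amplitude_mV = amplitude_mV,
                            rate_bpm = jet_rate_bpm), class = "trigger_train")
  } else {
    train <- pacer_input_signal(jet_rate_bpm, amplitude_mV, duration_s,
                                phase_ms)
  }

  trigger_channel <- if (wiring$ventricular_wires_to == "atrial") "A" else "V"
  log <- pm_run(settings, train, duration_s * 1000, trigger_channel)
  attr(log, "wiring") <- wiring
  attr(log, "jet_rate_bpm") <- jet_rate_bpm

  if (include_trace) {
    tpl <- make_beat_template()
    trace <- generate_jet_trace(tpl, jet_rate_bpm, duration_s)
    trace <- lowpass_filter(trace)
    trace <- derive_monitor_leads(trace)
    trace <- annotate_pacing_spikes(trace, log)
    attr(log, "trace") <- trace
  }
  log
}

#' @export
print.avt_event_log <- function(x, ...) {
  n_pace <- sum(x$kind == "pace")
  n_sense <- sum(x$kind == "sense" & x$channel == "ventricle")
  cat(sprintf("<avt_event_log> %d events: %d ventricular senses, %d atrial paces\n",
              nrow(x), n_sense, n_pace))
  if (identical(attr(x, "note"), "device_off")) cat("  (device off)\n")
  invisible(x)
}
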