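# Ten-step operator-assessment protocol: session records, the 3/2/1-point
# rubric, session scoring with a verification simulation, cohort summaries.

#' Canonical protocol steps
#'
#' The ten working steps of the assessment protocol, in protocol order:
#' switch the device on (ON), choose the dual-sensing ventricular-pacing
#' mode (VDD), set ventricular sensing to maximal insensitivity (V-SENSE),
#' set the maximum tracking rate 10-20 bpm above the JET rate (MTR), set
#' the AV delay to the highest possible value (AV-DLY), set the PVARP to
#' 100 ms (PVARP), set the basic stimulation rate clearly below the JET
#' rate (RATE), measure the ventricular input signal with the pause
#' function (R-WAVE), tune atrial sensing to 50% of the measured signal
#' (A-SENSE), and connect the pacing wires swapped, ventricular pair first
#' (WIRES).
#'
#' @format Character vector of step identifiers.
#' @export
PROTOCOL_STEPS <- c("ON", "VDD", "V-SENSE", "MTR", "AV-DLY", "PVARP",
                    "RATE", "R-WAVE", "A-SENSE", "WIRES")

#' Create a session record
#'
#' An operator's actions over the ten protocol steps: the parameter values
#' chosen, whether the intrinsic signal was measured, and the wire hookup.
#' Steps absent from `actions` count as not performed.
#'
#' @param jet_rate_bpm JET monitor rate during the session (default 200).
#' @param actions List of actions, each `list(step = <id>, ...)` with a
#'   `value` for parameter steps, `measured = TRUE/FALSE` for R-WAVE, and
#'   `swapped = TRUE/FALSE, order = "ventricular_first"/"atrial_first"` for
#'   WIRES. Later actions on the same step supersede earlier ones.
#' @param signal_amplitude_mV True intrinsic amplitude at the device input
#'   (default 5).
#' @return A `session_record`.
#' @export
session_record <- function(jet_rate_bpm = 200, actions = list(),
                           signal_amplitude_mV = 5) {
  validate_rate(jet_rate_bpm)
  for (a in actions) {
    if (is.null(a$step) || !a$step %in% PROTOCOL_STEPS)
      stop(sprintf("unknown protocol step '%s'", a$step %||% "<missing>"),
           call. = FALSE)
  }
  structure(list(jet_rate_bpm = jet_rate_bpm, actions = actions,
                 signal_amplitude_mV = signal_amplitude_mV),
            class = "session_record")
}

# last action recorded for a step, or NULL
session_action <- function(session, step_id) {
  hit <- NULL
  for (a in session$actions) if (identical(a$step, step_id)) hit <- a
  hit
}

#' Final device settings implied by a session
#'
#' Replays the recorded actions, in order, through [set_parameter()], so
#' device-enforced constraints (notably the AV-delay clamp, which depends
#' on the MTR and PVARP in force at programming time) apply exactly as they
#' would at the bedside.
#'
#' @param session A `session_record`.
#' @return `list(settings = <pacemaker_settings>, wiring = <wiring_plan> or
#'   NULL, measured = TRUE/FALSE)`.
#' @export
session_final_settings <- function(session) {
  s <- default_settings()
  wiring <- NULL
  measured <- FALSE
  par_of <- c("V-SENSE" = "v_sense_mV", "MTR" = "mtr_bpm",
              "AV-DLY" = "av_delay_ms", "PVARP" = "pvarp_ms",
              "RATE" = "basic_rate_bpm", "A-SENSE" = "a_sense_mV")
  for (a in session$actions) {
    if (a$step == "ON") s <- set_parameter(s, "power_on", isTRUE(a$value))
    else if (a$step == "VDD") s <- set_parameter(s, "mode", a$value)
    else if (a$step == "R-WAVE") measured <- isTRUE(a$measured)
    else if (a$step == "WIRES") {
      wiring <- if (isTRUE(a$swapped))
        connect_wires("atrial", "ventricular",
                      a$order %||% "ventricular_first")
      else
        connect_wires("ventricular", "atrial",
                      a$order %||% "ventricular_first")
    } else s <- set_parameter(s, par_of[[a$step]], a$value)
  }
  list(settings = s, wiring = wiring, measured = measured)
}

#' Score one protocol step
#'
#' Applies the 3/2/1-point rubric (correct / minor mistake / major mistake)
#' to a session. With J the JET monitor rate:
#' \describe{
#'   \item{ON}{switched on: 3; otherwise 1.}
#'   \item{VDD}{VDD mode chosen: 3; otherwise 1.}
#'   \item{V-SENSE}{maximal insensitivity ([V_SENSE_MAX]): 3; anything else
#'     leaves the device out of effective VAT: 1.}
#'   \item{MTR}{within J+10..J+20: 3; equal to J (allows very short AP-VS
#'     intervals): 2; untouched or any other value: 1.}
#'   \item{AV-DLY}{final value equal to [max_av_delay()] for the final MTR
#'     and PVARP: 3; another deliberate value: 2; untouched: 1.}
#'   \item{PVARP}{100 ms: 3; anything else impedes effective AVT pacing: 1.}
#'   \item{RATE}{more than 20 bpm below J: 3; within 20 bpm below J (risky
#'     if the tachycardia slows): 2; at or above J, or untouched: 1.}
#'   \item{R-WAVE}{measured via the pause function: 3; recorded as skipped:
#'     2 (protocol deviation, not necessarily harmful); absent from the
#'     record: 1, like other unperformed steps.}
#'   \item{A-SENSE}{50% of the intrinsic amplitude (within 0.1 mV): 3;
#'     another value that still senses the signal: 2; untouched default or
#'     a threshold at/above the signal: 1.}
#'   \item{WIRES}{swapped with the ventricular pair connected first: 3;
#'     swapped, atrial first: 2; not swapped: 1.}
#' }
#'
#' @param step_id One of [PROTOCOL_STEPS].
#' @param session A `session_record`.
#' @param jet_rate_bpm JET rate (defaults to the session's).
#' @return A `step_score`: `step_id`, `points` (1, 2 or 3), `rationale`,
#'   `performed`.
#' @examples
#' s <- session_record(200, list(list(step = "MTR", value = 200)))
#' score_step("MTR", s)$points  # 2
#' @export
score_step <- function(step_id, session, jet_rate_bpm = session$jet_rate_bpm) {
  if (!step_id %in% PROTOCOL_STEPS)
    stop(sprintf("unknown protocol step '%s'", step_id), call. = FALSE)
  a <- session_action(session, step_id)
  J <- jet_rate_bpm
  amp <- session$signal_amplitude_mV
  performed <- !is.null(a)
  res <- switch(step_id,
    "ON" = if (performed && isTRUE(a$value)) c(3, "device switched on")
           else c(1, "device not switched on"),
    "VDD" = if (performed && identical(a$value, "VDD"))
              c(3, "VDD mode selected")
            else c(1, "VDD mode not selected"),
    "V-SENSE" = if (performed && a$value >= V_SENSE_MAX)
                  c(3, "ventricular sensing at maximal insensitivity; device in effective VAT")
                else c(1, "ventricular sensing not maximally insensitive; no switch into VAT"),
    "MTR" = {
      if (!performed) c(1, "MTR left at default")
      else if (a$value >= J + 10 && a$value <= J + 20)
        c(3, "MTR 10-20 bpm above the JET rate")
      else if (a$value == J)
        c(2, "MTR equal to the monitor rate; allows very short AP-VS intervals")
      else c(1, "MTR neither 10-20 bpm above nor equal to the JET rate")
    },
    "AV-DLY" = {
      if (!performed) c(1, "AV delay left at default")
      else {
        fin <- session_final_settings(session)$settings
        cap <- max_av_delay(fin$mtr_bpm, fin$pvarp_ms)
        if (fin$av_delay_ms == cap)
          c(3, "AV delay at the highest possible value")
        else c(2, "individually chosen AV delay below the maximum")
      }
    },
    "PVARP" = if (performed && a$value == 100) c(3, "PVARP set to 100 ms")
              else c(1, "PVARP not set to 100 ms; impedes effective AVT pacing"),
    "RATE" = {
      v <- if (performed) a$value else default_settings()$basic_rate_bpm
      if (performed && v < J - 20)
        c(3, "basic rate clearly below the JET rate")
      else if (performed && v < J)
        c(2, "basic rate less than 20 bpm below the JET rate; risky if the tachycardia slows")
      else if (performed)
        c(1, "basic rate at or above the JET rate; asynchronous atrial stimulation")
      else c(1, "basic rate left at default, above the JET rate; asynchronous atrial stimulation")
    },
    "R-WAVE" = {
      if (!performed) c(1, "signal measurement not addressed")
      else if (isTRUE(a$measured))
        c(3, "intrinsic signal measured via the pause function")
      else c(2, "signal measurement skipped; protocol deviation")
    },
    "A-SENSE" = {
      if (!performed)
        c(1, "atrial sensitivity left at default; signal below threshold")
      else if (abs(a$value - amp / 2) <= 0.1)
        c(3, "atrial sensitivity at 50% of the measured signal")
      else if (a$value < amp)
        c(2, "atrial sensitivity senses the signal but is not the 50% setting")
      else c(1, "atrial sensing threshold at/above the signal; sensing impaired")
    },
    "WIRES" = {
      if (!performed) c(1, "wires not connected")
      else if (!isTRUE(a$swapped))
        c(1, "wires not swapped; no AVT configuration")
      else if (identical(a$order %||% "ventricular_first", "ventricular_first"))
        c(3, "wires swapped, ventricular pair connected first")
      else c(2, "wires swapped but atrial pair connected first")
    })
  structure(list(step_id = step_id, points = as.integer(res[1L]),
                 rationale = res[2L], performed = performed),
            class = "step_score")
}

#' Score a full session
#'
#' Scores all ten protocol steps, totals the points (10..30), and -- unless
#' `simulate = FALSE` -- runs a verification simulation of the final
#' settings through the recorded wiring and classifies the resulting pacing
#' behavior.
#'
#' @param session A `session_record`.
#' @param simulate Run the verification simulation (default TRUE).
#' @param sim_duration_s Verification run length in seconds (default 15).
#' @return A `session_report`: `scores` (data frame), `total`, `behavior`
#'   (a `behavior_label`, or NULL when not simulated), `final_settings`.
#' @export
score_session <- function(session, simulate = TRUE, sim_duration_s = 15) {
  scores <- do.call(rbind, lapply(PROTOCOL_STEPS, function(st) {
    sc <- score_step(st, session)
    data.frame(step = st, points = sc$points, rationale = sc$rationale,
               performed = sc$performed, stringsAsFactors = FALSE)
  }))
  total <- sum(scores$points)
  behavior <- NULL
  fin <- session_final_settings(session)
  if (simulate) {
    wiring <- fin$wiring %||% connect_wires()
    log <- run_simulation(fin$settings, wiring, session$jet_rate_bpm,
                          sim_duration_s,
                          amplitude_mV = session$signal_amplitude_mV)
    behavior <- classify_behavior(log, session$jet_rate_bpm, fin$settings)
  }
  structure(list(scores = scores, total = total, behavior = behavior,
                 final_settings = fin$settings,
                 jet_rate_bpm = session$jet_rate_bpm),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> JET %g bpm, total %d/30\n",
              x$jet_rate_bpm, x$total))
  for (i in seq_len(nrow(x$scores)))
    cat(sprintf("  %-8s %d  %s\n", x$scores$step[i], x$scores$points[i],
                x$scores$rationale[i]))
  if (!is.null(x$behavior))
    cat(sprintf("  verification run: %s\n", x$behavior$label))
  invisible(x)
}

#' Summarize a cohort of session reports
#'
#' Per-step counts of 1-, 2- and 3-point outcomes across reports.
#'
#' @param reports List of `session_report` objects.
#' @return Data frame with columns `step`, `pts1`, `pts2`, `pts3`.
#' @export
summarize_cohort <- function(reports) {
  if (!length(reports)) stop("no reports to summarize", call. = FALSE)
  tab <- do.call(rbind, lapply(PROTOCOL_STEPS, function(st) {
    pts <- vapply(reports, function(r)
      r$scores$points[r$scores$step == st], 1L)
    data.frame(step = st,
               pts1 = sum(pts == 1L), pts2 = sum(pts == 2L),
               pts3 = sum(pts == 3L), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Cohort table as markdown
#'
#' @param tab Output of [summarize_cohort()].
#' @return Character vector of markdown lines.
#' @export
cohort_table_markdown <- function(tab) {
  c("| step | 1 pt | 2 pts | 3 pts |",
    "|------|------|-------|-------|",
    sprintf("| %s | %d | %d | %d |", tab$step, tab$pts1, tab$pts2, tab$pts3))
}
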