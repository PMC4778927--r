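# External pacemaker model: programmable settings with device-enforced
# constraints, and the beat-to-beat timing cycle (sensing, triggered pacing,
# refractory periods, upper-rate deferral, escape pacing, crosstalk
# self-inhibition in effective VDD).

#' Programmable ranges of the modeled device
#'
#' @format Named list; each numeric entry is `c(min, max)` in the
#'   parameter's unit, `mode` is the set of mode codes.
#' @export
PM_PARAM_RANGES <- list(
  mode           = c("VDD", "VAT", "AAI", "VVI", "OFF"),
  mtr_bpm        = c(80, 300),
  av_delay_ms    = c(0, 300),
  pvarp_ms       = c(0, 500),
  basic_rate_bpm = c(30, 300),
  a_sense_mV     = c(0.5, 20),
  v_sense_mV     = c(0.5, 20),
  a_stim_V       = c(0.1, 18),
  v_stim_V       = c(0.1, 18),
  crosstalk_mV   = c(0, 20)
)

#' Sensitivity value meaning "maximal insensitivity"
#'
#' Top of the programmable sensing-threshold range (20 mV). Programming the
#' ventricular channel here effectively disables ventricular sensing, which
#' is what switches the VDD device into effective VAT behavior in the
#' swapped-lead configuration.
#'
#' @export
V_SENSE_MAX <- 20

#' Factory default settings
#'
#' The power-on state of the modeled external pacemaker: mode VDD, maximum
#' tracking rate 230 bpm, basic stimulation rate 210 bpm, PVARP 200 ms,
#' AV delay 50 ms, ventricular stimulation voltage 12 V, atrial and
#' ventricular sensing thresholds 8 mV each; device switched off.
#'
#' @return A `pacemaker_settings` object.
#' @examples
#' s <- default_settings()
#' s$mtr_bpm        # 230
#' s$basic_rate_bpm # 210
#' @export
default_settings <- function() {
  structure(list(
    mode = "VDD",
    mtr_bpm = 230,
    av_delay_ms = 50,
    pvarp_ms = 200,
    basic_rate_bpm = 210,
    a_sense_mV = 8,
    v_sense_mV = 8,
    a_stim_V = 12,
    v_stim_V = 12,
    crosstalk_mV = 10,
    power_on = FALSE
  ), class = "pacemaker_settings")
}

#' @export
print.pacemaker_settings <- function(x, ...) {
  cat(sprintf("<pacemaker_settings> mode %s (%s), power %s\n",
              x$mode, effective_mode(x), if (x$power_on) "ON" else "OFF"))
  cat(sprintf("  MTR %g bpm | RATE %g bpm | AV-DLY %g ms | PVARP %g ms\n",
              x$mtr_bpm, x$basic_rate_bpm, x$av_delay_ms, x$pvarp_ms))
  cat(sprintf("  A-SENSE %g mV | V-SENSE %g mV | A-STIM %g V | V-STIM %g V\n",
              x$a_sense_mV, x$v_sense_mV, x$a_stim_V, x$v_stim_V))
  invisible(x)
}

#' Maximum programmable AV delay
#'
#' The device bounds the AV delay so that AV delay + PVARP still fits within
#' one upper-rate interval: the largest multiple of 10 ms `d` with
#' `d + pvarp_ms <= 60000 / mtr_bpm`, floored at 0 ms and capped at the
#' device's 300 ms programming limit. With the factory MTR (230 bpm) and
#' PVARP (200 ms) this evaluates to 60 ms.
#'
#' @param mtr_bpm Maximum tracking rate in bpm (> 0).
#' @param pvarp_ms Postventricular atrial refractory period in ms (>= 0).
#' @return Maximum programmable AV delay in ms.
#' @examples
#' max_av_delay(230, 200)  # 60
#' max_av_delay(220, 100)  # 170
#' @export
max_av_delay <- function(mtr_bpm, pvarp_ms) {
  stopifnot(mtr_bpm > 0, pvarp_ms >= 0)
  d <- 10 * floor((60000 / mtr_bpm - pvarp_ms) / 10)
  min(max(d, 0), PM_PARAM_RANGES$av_delay_ms[2L])
}

#' Program one pacemaker parameter
#'
#' Applies a value with device-side validation: unknown names and
#' out-of-range values are rejected; the AV delay must be a multiple of
#' 10 ms and is silently clamped down to [max_av_delay()] (as the real dial
#' stops there); lowering the headroom by changing `mtr_bpm` or `pvarp_ms`
#' clamps an already-programmed AV delay the same way. A clamp is reported
#' in the `"clamped_av_delay"` attribute of the returned settings.
#'
#' @param settings A `pacemaker_settings` object.
#' @param name Parameter name (a field of [default_settings()]).
#' @param value New value.
#' @return Updated `pacemaker_settings`.
#' @examples
#' s <- set_parameter(default_settings(), "av_delay_ms", 170)
#' s$av_delay_ms  # 60: clamped by MTR 230 / PVARP 200
#' @export
set_parameter <- function(settings, name, value) {
  known <- c(names(PM_PARAM_RANGES), "power_on")
  if (!name %in% known)
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  if (name == "power_on") {
    stopifnot(is.logical(value), length(value) == 1L)
    settings$power_on <- value
    return(settings)
  }
  if (name == "mode") {
    if (!value %in% PM_PARAM_RANGES$mode)
      stop(sprintf("unknown mode '%s'", value), call. = FALSE)
    settings$mode <- value
    return(settings)
  }
  rng <- PM_PARAM_RANGES[[name]]
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < rng[1L] || value > rng[2L])
    stop(sprintf("%s = %s outside the programmable range [%g, %g]",
                 name, format(value), rng[1L], rng[2L]), call. = FALSE)
  value <- as.numeric(value)
  if (name == "av_delay_ms") {
    if (value %% 10 != 0)
      stop("av_delay_ms is programmable in 10 ms steps", call. = FALSE)
    cap <- max_av_delay(settings$mtr_bpm, settings$pvarp_ms)
    settings$av_delay_ms <- min(value, cap)
    if (value > cap) attr(settings, "clamped_av_delay") <- TRUE
    return(settings)
  }
  settings[[name]] <- value
  if (name %in% c("mtr_bpm", "pvarp_ms")) {
    cap <- max_av_delay(settings$mtr_bpm, settings$pvarp_ms)
    if (settings$av_delay_ms > cap) {
      settings$av_delay_ms <- cap
      attr(settings, "clamped_av_delay") <- TRUE
    }
  }
  settings
}

#' Effective pacing mode
#'
#' A VDD device behaves as VAT (pure triggered pacing) only once the
#' ventricular channel has been programmed to maximal insensitivity
#' ([V_SENSE_MAX]); otherwise pace-associated crosstalk can still be sensed
#' there and inhibit triggered pacing. Non-VDD modes are reported as-is
#' (they are not AVT-capable configurations).
#'
#' @param settings A `pacemaker_settings` object.
#' @return `"VAT"`, `"VDD"`, or the programmed mode for non-VDD modes.
#' @export
effective_mode <- function(settings) {
  if (settings$mode != "VDD") return(settings$mode)
  if (settings$v_sense_mV >= V_SENSE_MAX) "VAT" else "VDD"
}

# ---------------------------------------------------------------------------
# Timing-cycle engine.
#
# Channel naming is physiological: the trigger signal (the sensed QRS,
# arriving on the device's atrial port in the swapped-lead rig) is logged on
# channel "ventricle" (kind "sense" = VS); delivered stimuli are logged on
# channel "atrium" (kind "pace" = AP). Crosstalk/inhibition events live on
# channel "device".

new_event_rows <- function(time_ms, channel, kind, detail = NA_character_,
                           amplitude_mV = NA_real_) {
  data.frame(time_ms = time_ms, channel = channel, kind = kind,
             detail = detail, amplitude_mV = amplitude_mV,
             stringsAsFactors = FALSE)
}

#' Fresh device timing state
#'
#' @param settings A `pacemaker_settings` object.
#' @param t0 Time the device starts running, ms (default 0).
#' @return A `pm_state` object: current time, last pace time, refractory
#'   end, pending triggered pace, escape deadline, inhibition flag,
#'   effective mode, pause flag.
#' @export
pm_state_new <- function(settings, t0 = 0) {
  structure(list(
    now = t0,
    last_pace_time_ms = NA_real_,
    refractory_until_ms = -Inf,
    pending_pace_time_ms = NA_real_,
    pending_detail = NA_character_,
    escape_deadline_ms = t0 + 60000 / settings$basic_rate_bpm,
    inhibit_next = FALSE,
    effective_mode = effective_mode(settings),
    paused = FALSE
  ), class = "pm_state")
}

# earliest device-scheduled action; escape paces are deferred to the
# upper-rate interval as well, so no delivered pace can violate it
next_action <- function(state, settings) {
  uri <- 60000 / settings$mtr_bpm
  esc <- state$escape_deadline_ms
  if (!is.na(state$last_pace_time_ms))
    esc <- max(esc, state$last_pace_time_ms + uri)
  p <- state$pending_pace_time_ms
  if (!is.na(p) && p <= esc) list(time = p, detail = state$pending_detail)
  else list(time = esc, detail = "escape")
}

deliver_pace <- function(state, settings, tp, detail) {
  ev <- new_event_rows(tp, "atrium", "pace", detail)
  state$last_pace_time_ms <- tp
  state$refractory_until_ms <- tp + settings$pvarp_ms
  state$escape_deadline_ms <- tp + 60000 / settings$basic_rate_bpm
  state$pending_pace_time_ms <- NA_real_
  state$pending_detail <- NA_character_
  if (state$effective_mode == "VDD") {
    sensed <- settings$crosstalk_mV > settings$v_sense_mV
    ev <- rbind(ev, new_event_rows(
      tp, "device", "crosstalk",
      if (sensed) "sensed" else "unsensed", settings$crosstalk_mV))
    if (sensed) state$inhibit_next <- TRUE
  }
  list(state = state, events = ev)
}

# fire every scheduled action due at or before `upto`
fire_due <- function(state, settings, upto) {
  evs <- list()
  repeat {
    act <- next_action(state, settings)
    if (act$time > upto) break
    d <- deliver_pace(state, settings, act$time, act$detail)
    state <- d$state
    evs[[length(evs) + 1L]] <- d$events
  }
  list(state = state, events = do.call(rbind, evs))
}

process_trigger <- function(state, settings, ts, amp) {
  if (amp <= settings$a_sense_mV)
    return(list(state = state,
                events = new_event_rows(ts, "ventricle", "subthreshold",
                                        amplitude_mV = amp)))
  if (ts < state$refractory_until_ms)
    return(list(state = state,
                events = new_event_rows(ts, "ventricle", "refractory_drop",
                                        amplitude_mV = amp)))
  ev <- new_event_rows(ts, "ventricle", "sense", amplitude_mV = amp)
  if (state$inhibit_next) {
    state$inhibit_next <- FALSE
    ev <- rbind(ev, new_event_rows(ts, "device", "inhibit", "crosstalk"))
  } else if (is.na(state$pending_pace_time_ms)) {
    tp <- ts + settings$av_delay_ms
    detail <- "triggered"
    if (!is.na(state$last_pace_time_ms)) {
      uri <- 60000 / settings$mtr_bpm
      if (tp < state$last_pace_time_ms + uri) {
        tp <- state$last_pace_time_ms + uri
        detail <- "deferred"
      }
    }
    state$pending_pace_time_ms <- tp
    state$pending_detail <- detail
  }
  list(state = state, events = ev)
}

# a signal presented on the device's ventricular channel (straight wiring,
# or the crosstalk path): if sensed it cancels triggered pacing
process_v_signal <- function(state, settings, ts, amp) {
  if (amp <= settings$v_sense_mV)
    return(list(state = state,
                events = new_event_rows(ts, "device", "subthreshold",
                                        amplitude_mV = amp)))
  ev <- new_event_rows(ts, "device", "sense", amplitude_mV = amp)
  if (!is.na(state$pending_pace_time_ms)) {
    state$pending_pace_time_ms <- NA_real_
    state$pending_detail <- NA_character_
    ev <- rbind(ev, new_event_rows(ts, "device", "inhibit", "v_channel"))
  } else {
    state$inhibit_next <- TRUE
  }
  list(state = state, events = ev)
}

#' Advance the device by one event
#'
#' Incremental interface to the timing cycle. The event is either a sensed
#' signal (`list(type = "sense", time_ms =, amplitude_mV =, channel =)`,
#' channel `"A"` for the device's atrial/trigger input, `"V"` for its
#' ventricular input) or a clock tick (`list(type = "tick", time_ms =)`).
#' Device-scheduled paces due up to the event time fire first, in order.
#'
#' @param state A `pm_state` from [pm_state_new()].
#' @param settings A `pacemaker_settings` object (power must be on).
#' @param event Event list, see Details.
#' @return `list(state = <new state>, events = <data frame of emitted
#'   events>)`; rows have `time_ms`, `channel`, `kind`, `detail`,
#'   `amplitude_mV`.
#' @export
step_device <- function(state, settings, event) {
  if (!isTRUE(settings$power_on))
    stop("device is switched off", call. = FALSE)
  if (!settings$mode %in% c("VDD", "VAT"))
    stop(sprintf("mode %s timing cycle is not modeled", settings$mode),
         call. = FALSE)
  t <- event$time_ms
  if (is.null(t) || t < state$now)
    stop("event time precedes current device time", call. = FALSE)
  fd <- fire_due(state, settings, t)
  state <- fd$state
  evs <- fd$events
  if (identical(event$type, "sense")) {
    pr <- if (identical(event$channel, "V"))
      process_v_signal(state, settings, t, event$amplitude_mV)
    else
      process_trigger(state, settings, t, event$amplitude_mV)
    state <- pr$state
    evs <- rbind(evs, pr$events)
  } else if (!identical(event$type, "tick")) {
    stop(sprintf("unknown event type '%s'", event$type), call. = FALSE)
  }
  state$now <- t
  list(state = state, events = evs)
}

#' Run the timing cycle over a trigger train
#'
#' Event-driven closed-form run of the device over `duration_ms`, with the
#' intrinsic trigger train presented on one device input.
#'
#' @param settings A `pacemaker_settings` object with `power_on = TRUE`.
#' @param train A `trigger_train` (see [pacer_input_signal()]).
#' @param duration_ms Run length in ms.
#' @param trigger_channel `"A"` (swapped-lead AVT configuration: the QRS
#'   arrives on the device's atrial input) or `"V"` (straight wiring).
#' @return An event log (`data.frame`, class `avt_event_log`) with columns
#'   `time_ms`, `channel` (atrium/ventricle/device), `kind` (sense, pace,
#'   refractory_drop, subthreshold, crosstalk, inhibit), `detail` (for
#'   paces: triggered, deferred, escape), `amplitude_mV`.
#' @export
pm_run <- function(settings, train, duration_ms, trigger_channel = "A") {
  if (!isTRUE(settings$power_on))
    stop("device is switched off", call. = FALSE)
  state <- pm_state_new(settings, t0 = 0)
  evs <- list()
  times <- train$event_times_ms
  times <- times[times <= duration_ms]
  for (ts in times) {
    st <- step_device(state, settings, list(
      type = "sense", time_ms = ts, amplitude_mV = train$amplitude_mV,
      channel = trigger_channel))
    state <- st$state
    if (!is.null(st$events)) evs[[length(evs) + 1L]] <- st$events
  }
  st <- step_device(state, settings, list(type = "tick", time_ms = duration_ms))
  if (!is.null(st$events)) evs[[length(evs) + 1L]] <- st$events
  log <- do.call(rbind, evs)
  if (is.null(log)) log <- new_event_rows(numeric(0), character(0), character(0))
  log <- log[order(log$time_ms), ]
  rownames(log) <- NULL
  structure(log, class = c("avt_event_log", "data.frame"),
            settings = settings, duration_ms = duration_ms,
            trigger_channel = trigger_channel)
}

#' Measure the intrinsic signal with the pause function
#'
#' Suspends pacing and reports the amplitude of the intrinsic ventricular
#' signal as presented on the device's atrial channel, plus the recommended
#' atrial sensing threshold (50% of the measured amplitude).
#'
#' @param settings A `pacemaker_settings` object.
#' @param train A `trigger_train`.
#' @return An `r_wave_measurement`: `amplitude_mV` (NA if no signal),
#'   `no_signal` flag, `recommended_a_sense_mV`.
#' @export
measure_r_wave <- function(settings, train) {
  if (length(train$event_times_ms) == 0L)
    return(structure(list(amplitude_mV = NA_real_, no_signal = TRUE,
                          recommended_a_sense_mV = NA_real_),
                     class = "r_wave_measurement"))
  structure(list(amplitude_mV = train$amplitude_mV, no_signal = FALSE,
                 recommended_a_sense_mV = train$amplitude_mV / 2),
            class = "r_wave_measurement")
}

#' @export
print.r_wave_measurement <- function(x, ...) {
  if (x$no_signal) cat("<r_wave_measurement> no signal\n")
  else cat(sprintf(
    "<r_wave_measurement> %.1f mV (recommended A-SENSE %.1f mV)\n",
    x$amplitude_mV, x$recommended_a_sense_mV))
  invisible(x)
}
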