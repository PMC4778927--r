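# Canned session records: one fixture per reported mistake pattern, plus a
# replay of the ten-operator cohort whose per-step score distribution the
# assessment summary reproduces.

act <- function(step, ...) c(list(step = step), list(...))

# protocol-correct action list at monitor rate J. PVARP is programmed
# before the AV delay so the AV-delay clamp is computed against the final
# refractory period; the AV delay itself is dialed to the device maximum
# (attempting the 300 ms programming limit ends at the clamp).
perfect_actions <- function(J = 200, amplitude_mV = 5) {
  list(
    act("ON", value = TRUE),
    act("VDD", value = "VDD"),
    act("V-SENSE", value = V_SENSE_MAX),
    act("MTR", value = J + 20),
    act("PVARP", value = 100),
    act("AV-DLY", value = 300),
    act("RATE", value = 100),
    act("R-WAVE", measured = TRUE),
    act("A-SENSE", value = amplitude_mV / 2),
    act("WIRES", swapped = TRUE, order = "ventricular_first")
  )
}

drop_step <- function(actions, step)
  Filter(function(a) !identical(a$step, step), actions)

replace_step <- function(actions, step, action) {
  lapply(actions, function(a) if (identical(a$step, step)) action else a)
}

#' Canned mistake-pattern sessions
#'
#' One session record per reported mistake pattern at a monitor rate of
#' 200 bpm, each derived from the perfect session by a single deviation:
#' `perfect`, `vsense_untouched`, `mtr_equal` (MTR = monitor rate),
#' `mtr_untouched`, `pvarp_untouched`, `rate_190` (within 20 bpm of the JET
#' rate), `rate_untouched`, `rwave_skipped` (A-SENSE still correct),
#' `asense_untouched`, `wires_atrial_first`.
#'
#' @param jet_rate_bpm Monitor rate (default 200).
#' @param amplitude_mV Intrinsic signal amplitude (default 5).
#' @return Named list of `session_record` objects.
#' @export
fixture_sessions <- function(jet_rate_bpm = 200, amplitude_mV = 5) {
  J <- jet_rate_bpm
  p <- perfect_actions(J, amplitude_mV)
  mk <- function(actions) session_record(J, actions, amplitude_mV)
  list(
    perfect = mk(p),
    vsense_untouched = mk(drop_step(p, "V-SENSE")),
    mtr_equal = mk(replace_step(p, "MTR", act("MTR", value = J))),
    mtr_untouched = mk(drop_step(p, "MTR")),
    pvarp_untouched = mk(drop_step(p, "PVARP")),
    rate_190 = mk(replace_step(p, "RATE", act("RATE", value = J - 10))),
    rate_untouched = mk(drop_step(p, "RATE")),
    rwave_skipped = mk(replace_step(p, "R-WAVE",
                                    act("R-WAVE", measured = FALSE))),
    asense_untouched = mk(drop_step(p, "A-SENSE")),
    wires_atrial_first = mk(replace_step(
      p, "WIRES", act("WIRES", swapped = TRUE, order = "atrial_first")))
  )
}

#' Replay of the ten-operator cohort
#'
#' Ten session records at a monitor rate of 200 bpm whose per-step score
#' distribution matches the reported cohort: every operator handled ON,
#' VDD and the wire swap; one missed maximal ventricular insensitivity;
#' MTR outcomes split 7/2/1 (correct / equal to the monitor rate /
#' untouched); half selected the maximum AV delay; three left the PVARP at
#' default; basic-rate outcomes split 3/3/4; eight skipped the signal
#' measurement; atrial-sensitivity outcomes split 3/5/2; half connected
#' the atrial wires first.
#'
#' @param jet_rate_bpm Monitor rate (default 200).
#' @param amplitude_mV Intrinsic signal amplitude (default 5).
#' @return List of ten `session_record` objects.
#' @export
cohort_sessions <- function(jet_rate_bpm = 200, amplitude_mV = 5) {
  J <- jet_rate_bpm
  base <- perfect_actions(J, amplitude_mV)
  mk <- function(actions) session_record(J, actions, amplitude_mV)

  lapply(1:10, function(i) {
    a <- base
    if (i == 1L) a <- drop_step(a, "V-SENSE")               # V-SENSE: 1 pt
    if (i %in% 8:9) a <- replace_step(a, "MTR", act("MTR", value = J))
    if (i == 10L) a <- drop_step(a, "MTR")
    if (i %in% 6:8) a <- drop_step(a, "PVARP")              # PVARP: 1 pt
    if (i %in% 6:10) {                                      # AV-DLY: 2 pts
      av <- if (i %in% 6:8) 60 else 100   # below the respective maximum
      a <- replace_step(a, "AV-DLY", act("AV-DLY", value = av))
    }
    if (i %in% 4:6) a <- replace_step(a, "RATE", act("RATE", value = J - 10))
    if (i %in% 7:10) a <- drop_step(a, "RATE")
    if (i >= 3L) a <- replace_step(a, "R-WAVE",
                                   act("R-WAVE", measured = FALSE))
    if (i %in% 4:8) a <- replace_step(a, "A-SENSE",
                                      act("A-SENSE", value = 4))
    if (i %in% 9:10) a <- drop_step(a, "A-SENSE")
    if (i %in% 6:10) a <- replace_step(
      a, "WIRES", act("WIRES", swapped = TRUE, order = "atrial_first"))
    mk(a)
  })
}
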