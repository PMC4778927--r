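# JET ECG source: beat template synthesis, rate-by-resampling trace
# generation, the hardware-style low-pass, monitor-lead derivation and the
# pacemaker trigger signal.

#' Rates selectable on the JET source
#'
#' The simulated source offers heart rates from 130 to 240 bpm in 10 bpm
#' increments, like the rotary switch on the bench device it emulates.
#'
#' @format Integer vector of legal rates (bpm).
#' @export
JET_RATES <- seq(130L, 240L, by = 10L)

#' Validate a JET source rate
#'
#' @param rate_bpm Heart rate in bpm.
#' @return `rate_bpm`, unchanged, if it is one of [JET_RATES].
#' @examples
#' validate_rate(200)
#' @export
validate_rate <- function(rate_bpm) {
  if (!is.numeric(rate_bpm) || length(rate_bpm) != 1L || !is.finite(rate_bpm))
    stop("rate_bpm must be a single finite number", call. = FALSE)
  if (!(rate_bpm %in% JET_RATES))
    stop(sprintf(
      "JET rate %s bpm is not selectable; legal rates are %d-%d bpm in steps of 10",
      format(rate_bpm), min(JET_RATES), max(JET_RATES)), call. = FALSE)
  rate_bpm
}

#' Default beat morphology for the JET template
#'
#' Sum-of-Gaussians description of one junctional beat: Q, R, S and T
#' components only -- deliberately no P component. Amplitudes in mV on the
#' lead II scale, centers and widths in ms within the beat window.
#'
#' @return Named list of components, each `list(amp, center_ms, sd_ms)`.
#' @export
default_beat_morphology <- function() {
  list(
    q = list(amp = -0.10, center_ms = 110, sd_ms = 4),
    r = list(amp =  1.00, center_ms = 120, sd_ms = 6),
    s = list(amp = -0.15, center_ms = 132, sd_ms = 4),
    # T ends early enough that the 120 ms pre-QRS window stays quiet even
    # when playback at 240 bpm compresses the whole beat to half length
    t = list(amp =  0.25, center_ms = 280, sd_ms = 25)
  )
}

#' Synthesize the stored JET beat template
#'
#' Builds the digitized single-beat array the source plays back: a narrow
#' QRS complex followed by a T wave, with no P wave. The template is defined
#' at a base heart rate; playback at other rates time-scales the whole beat
#' (see [generate_jet_trace()]).
#'
#' @param morphology Component list as from [default_beat_morphology()].
#' @param base_rate_bpm Heart rate at which the template plays back
#'   unscaled (beat window = 60000/base_rate_bpm ms). Default 120.
#' @param fs Template sampling rate in Hz. Default 1000.
#' @return An object of class `beat_template` with fields `samples` (mV),
#'   `fs`, `base_rate_bpm`, `r_peak_index`, `qrs_onset_index`,
#'   `qrs_offset_index`.
#' @details The constructor enforces the template invariants: a unique R
#'   peak, baseline first/last samples (continuous tiling), QRS width at the
#'   base rate no wider than 80 ms, and no deflection exceeding 2% of the
#'   R-peak amplitude in the 120 ms window preceding QRS onset (wrapping
#'   into the previous beat), which is the "no P wave" property.
#' @export
make_beat_template <- function(morphology = default_beat_morphology(),
                               base_rate_bpm = 120, fs = 1000) {
  stopifnot(base_rate_bpm > 0, fs > 0)
  beat_ms <- 60000 / base_rate_bpm
  tt <- seq(0, beat_ms - 1000 / fs, by = 1000 / fs)
  x <- rep(0, length(tt))
  for (g in morphology)
    x <- x + g$amp * exp(-((tt - g$center_ms)^2) / (2 * g$sd_ms^2))

  r_peak <- which.max(x)
  rpk <- x[r_peak]
  thr <- 0.02 * rpk
  # QRS bounds: contiguous supra-threshold region around the R peak
  onset <- r_peak
  while (onset > 1L && abs(x[onset - 1L]) > thr) onset <- onset - 1L
  offset <- r_peak
  n <- length(x)
  while (offset < n && abs(x[offset + 1L]) > thr) offset <- offset + 1L

  tpl <- structure(list(
    samples = x, fs = fs, base_rate_bpm = base_rate_bpm,
    r_peak_index = r_peak, qrs_onset_index = onset,
    qrs_offset_index = offset), class = "beat_template")
  validate_beat_template(tpl)
  tpl
}

#' Check beat-template invariants
#'
#' @param template A `beat_template`.
#' @return The template, invisibly; stops with a descriptive error on the
#'   first violated invariant.
#' @export
validate_beat_template <- function(template) {
  x <- template$samples
  n <- length(x)
  fs <- template$fs
  rpk <- x[template$r_peak_index]
  if (sum(x == max(x)) != 1L)
    stop("beat template must have a unique R peak", call. = FALSE)
  if (abs(x[1L]) >= 0.01 * rpk || abs(x[n]) >= 0.01 * rpk)
    stop("beat template must start and end at baseline (|amp| < 1% of R peak)",
         call. = FALSE)
  qrs_ms <- (template$qrs_offset_index - template$qrs_onset_index) * 1000 / fs
  if (qrs_ms > 80)
    stop(sprintf("QRS width %.1f ms exceeds 80 ms at the base rate", qrs_ms),
         call. = FALSE)
  # no-P-wave window: 120 ms before QRS onset, wrapping into the previous beat
  win <- ceiling(120 * fs / 1000)
  idx <- ((template$qrs_onset_index - seq_len(win) - 1L) %% n) + 1L
  if (max(abs(x[idx])) > 0.02 * rpk)
    stop("P-like deflection: amplitude exceeds 2% of the R peak in the 120 ms window before QRS onset",
         call. = FALSE)
  invisible(template)
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf(
    "<beat_template> %d samples @ %g Hz, base rate %g bpm, R peak %.2f mV\n",
    length(x$samples), x$fs, x$base_rate_bpm, max(x$samples)))
  cat(sprintf("  QRS: %.0f-%.0f ms (R apex %.0f ms), no P wave\n",
              (x$qrs_onset_index - 1) * 1000 / x$fs,
              (x$qrs_offset_index - 1) * 1000 / x$fs,
              (x$r_peak_index - 1) * 1000 / x$fs))
  invisible(x)
}

#' Construct a waveform trace
#'
#' @param fs Sampling rate in Hz.
#' @param channels Named list of equal-length amplitude vectors (mV).
#' @param annotations Optional data frame with `time_ms` and `label`.
#' @return A `waveform_trace`.
#' @export
waveform_trace <- function(fs, channels, annotations = NULL) {
  new_waveform_trace(fs, channels, annotations)
}

new_waveform_trace <- function(fs, channels, annotations = NULL) {
  if (is.null(annotations))
    annotations <- data.frame(time_ms = numeric(0), label = character(0))
  lens <- vapply(channels, length, 1L)
  if (length(unique(lens)) > 1L)
    stop("all trace channels must have equal length", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(list(fs = fs, channels = channels, annotations = annotations),
            class = "waveform_trace")
}

#' @export
print.waveform_trace <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf("<waveform_trace> %d samples @ %g Hz (%.2f s), channels: %s\n",
              n, x$fs, n / x$fs, paste(names(x$channels), collapse = ", ")))
  if (nrow(x$annotations))
    cat(sprintf("  %d annotations (%s...)\n", nrow(x$annotations),
                paste(head(x$annotations$label, 3L), collapse = ", ")))
  invisible(x)
}

#' Duration of a trace in milliseconds
#' @param trace A `waveform_trace`.
#' @export
trace_duration_ms <- function(trace) {
  length(trace$channels[[1L]]) / trace$fs * 1000
}

#' @export
as.data.frame.waveform_trace <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cbind(data.frame(time_ms = (seq_len(n) - 1) * 1000 / x$fs),
        as.data.frame(x$channels))
}

# Fixed divider weights applied to the single-ended source signal so the
# derived lead II (F - R) reproduces the template on its native scale.
ELECTRODE_WEIGHTS <- c(R = -1 / 3, L = 1 / 3, F = 2 / 3, N = 0)

#' Generate a JET electrocardiogram trace
#'
#' Plays the stored beat array back at the requested rate: the whole beat is
#' time-scaled by `base_rate_bpm / rate_bpm` and tiled, faithful to a device
#' that reads one digitized beat at a rate-dependent sampling clock (so a
#' higher rate compresses the QRS as well). Electrode channels R, L, F, N
#' are produced with fixed divider weights chosen so lead II (= F - R)
#' equals the template signal.
#'
#' @param template A `beat_template`.
#' @param rate_bpm Playback heart rate, one of [JET_RATES].
#' @param duration_s Trace duration in seconds.
#' @param fs Output sampling rate in Hz (>= 500).
#' @param preserve_qrs_width If `TRUE`, only the diastolic interval is
#'   stretched/compressed and the QRS-T complex keeps its base-rate
#'   duration. Off by default: the emulated hardware rescales everything.
#' @return A `waveform_trace` with channels R, L, F, N.
#' @export
generate_jet_trace <- function(template, rate_bpm, duration_s, fs = 1000,
                               preserve_qrs_width = FALSE) {
  validate_rate(rate_bpm)
  if (fs < 500) stop("fs must be at least 500 Hz", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)

  beat_ms <- 60000 / template$base_rate_bpm
  rr <- 60000 / rate_bpm
  n_out <- round(duration_s * fs)
  t_out <- (seq_len(n_out) - 1) * 1000 / fs
  phase <- t_out %% rr                  # ms into the current beat
  tt <- (seq_along(template$samples) - 1) * 1000 / template$fs

  if (!preserve_qrs_width) {
    u <- phase * (beat_ms / rr)         # template time
  } else {
    # keep the complex at native speed; absorb the rate change in diastole
    split_ms <- min(beat_ms, rr)        # complex window cannot exceed the beat
    u <- ifelse(phase < split_ms, phase,
                split_ms + (phase - split_ms) *
                  (beat_ms - split_ms) / max(rr - split_ms, 1e-9))
  }
  s <- approx(tt, template$samples, xout = pmin(u, max(tt)), rule = 2)$y

  channels <- lapply(ELECTRODE_WEIGHTS, function(w) w * s)
  new_waveform_trace(fs, channels)
}

#' Two-section low-pass filter (the "2-in-1" output filter)
#'
#' Applies two cascaded identical first-order low-pass sections, each with
#' its -3 dB point at `cutoff_hz`, to every channel. The cascade gain at the
#' cutoff frequency is therefore 0.5.
#'
#' @param trace A `waveform_trace`.
#' @param cutoff_hz Cutoff frequency in Hz (default 159, as on the emulated
#'   output stage).
#' @return Filtered `waveform_trace`, same channels and length.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 159) {
  if (trace$fs <= 2 * cutoff_hz)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz cutoff (need fs > 2*cutoff)",
                 trace$fs, cutoff_hz), call. = FALSE)
  bf <- signal::butter(1, cutoff_hz / (trace$fs / 2), type = "low")
  channels <- lapply(trace$channels, function(ch) {
    as.numeric(signal::filter(bf, signal::filter(bf, ch)))
  })
  new_waveform_trace(trace$fs, channels, trace$annotations)
}

#' Derive the Einthoven monitor leads
#'
#' From electrode channels R (right arm), L (left arm) and F (foot) derives
#' lead I = L - R, lead II = F - R, lead III = F - L.
#'
#' @param trace A `waveform_trace` containing channels `R`, `L`, `F`.
#' @return The trace with channels `I`, `II`, `III` added.
#' @export
derive_monitor_leads <- function(trace) {
  for (ch in c("R", "L", "F"))
    if (is.null(trace$channels[[ch]]))
      stop(sprintf("electrode channel '%s' is missing", ch), call. = FALSE)
  ch <- trace$channels
  ch$I   <- ch$L - ch$R
  ch$II  <- ch$F - ch$R
  ch$III <- ch$F - ch$L
  new_waveform_trace(trace$fs, ch, trace$annotations)
}

#' Trigger signal presented at the pacemaker input
#'
#' The source's top output plugs supply one intrinsic-depolarization trigger
#' per beat at an impedance-adjusted amplitude. This is the signal the
#' pacemaker senses in the closed loop.
#'
#' @param rate_bpm JET rate, one of [JET_RATES].
#' @param amplitude_mV Intrinsic signal amplitude at the device input
#'   (default 5).
#' @param duration_s Train duration in seconds.
#' @param phase_ms Time of the first event (default 0).
#' @return An object of class `trigger_train` with fields `event_times_ms`
#'   and `amplitude_mV`.
#' @export
pacer_input_signal <- function(rate_bpm, amplitude_mV = 5, duration_s,
                               phase_ms = 0) {
  validate_rate(rate_bpm)
  if (amplitude_mV <= 0) stop("amplitude_mV must be positive", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  rr <- 60000 / rate_bpm
  k <- 0:floor((duration_s * 1000 - phase_ms) / rr)
  times <- phase_ms + k * rr
  times <- times[times < duration_s * 1000]
  structure(list(event_times_ms = times, amplitude_mV = amplitude_mV,
                 rate_bpm = rate_bpm), class = "trigger_train")
}

#' @export
print.trigger_train <- function(x, ...) {
  cat(sprintf("<trigger_train> %d events, %g bpm, %g mV\n",
              length(x$event_times_ms), x$rate_bpm, x$amplitude_mV))
  invisible(x)
}

#' Annotate atrial pacing spikes on a trace
#'
#' Adds, for each atrial pace in an event log, an `AP` annotation and a 2 ms
#' rectangular spike artifact on the lead channels -- the planned "show the
#' pacing spike on the monitor" improvement, realized as trace annotation.
#'
#' @param trace A `waveform_trace`.
#' @param event_log Event log from [pm_run()] / [run_simulation()] (or any
#'   data frame with `time_ms` and `kind` columns).
#' @param spike_mV Spike amplitude in mV (default 2).
#' @return Annotated `waveform_trace`.
#' @export
annotate_pacing_spikes <- function(trace, event_log, spike_mV = 2) {
  paces <- event_log$time_ms[event_log$kind == "pace"]
  if (!length(paces)) return(trace)
  dur <- trace_duration_ms(trace)
  if (any(paces < 0 | paces > dur))
    stop("pace events outside the trace duration", call. = FALSE)
  n <- length(trace$channels[[1L]])
  lead_ch <- intersect(c("I", "II", "III", "R", "L", "F"),
                       names(trace$channels))
  spike_len <- max(1L, round(2 / 1000 * trace$fs))  # 2 ms
  channels <- trace$channels
  for (tp in paces) {
    i0 <- floor(tp / 1000 * trace$fs) + 1L
    idx <- i0:min(n, i0 + spike_len - 1L)
    for (ch in lead_ch) channels[[ch]][idx] <- channels[[ch]][idx] + spike_mV
  }
  ann <- rbind(trace$annotations,
               data.frame(time_ms = paces, label = "AP"))
  new_waveform_trace(trace$fs, channels, ann[order(ann$time_ms), ])
}
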