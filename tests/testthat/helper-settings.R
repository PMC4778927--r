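# Protocol-correct device programming for a given monitor rate: effective
# VAT, MTR 20 bpm above the JET rate, PVARP 100 ms, maximum AV delay,
# atrial sensitivity at 50% of the 5 mV intrinsic signal.
protocol_settings <- function(jet_rate_bpm = 200, basic_rate_bpm = 100) {
  s <- default_settings()
  s <- set_parameter(s, "power_on", TRUE)
  s <- set_parameter(s, "v_sense_mV", V_SENSE_MAX)
  s <- set_parameter(s, "mtr_bpm", jet_rate_bpm + 20)
  s <- set_parameter(s, "pvarp_ms", 100)
  s <- set_parameter(s, "av_delay_ms",
                     max_av_delay(jet_rate_bpm + 20, 100))
  s <- set_parameter(s, "a_sense_mV", 2.5)
  set_parameter(s, "basic_rate_bpm", basic_rate_bpm)
}

# R-peak times (ms) of a single-channel signal: argmax of each contiguous
# region above half the global maximum
detect_r_peaks <- function(x, fs) {
  thr <- 0.5 * max(x)
  above <- x > thr
  starts <- which(above & !c(FALSE, head(above, -1L)))
  ends <- which(above & !c(tail(above, -1L), FALSE))
  peaks <- mapply(function(a, b) a - 1L + which.max(x[a:b]), starts, ends)
  (peaks - 1L) * 1000 / fs
}

# steady-state amplitude of a filtered sinusoid (skip the transient)
measured_gain <- function(freq_hz, fs, cutoff_hz = 159, duration_s = 1) {
  tt <- seq(0, duration_s, by = 1 / fs)
  tr <- waveform_trace(fs, list(x = sin(2 * pi * freq_hz * tt)))
  y <- lowpass_filter(tr, cutoff_hz)$channels$x
  max(abs(tail(y, round(length(y) / 2))))
}
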