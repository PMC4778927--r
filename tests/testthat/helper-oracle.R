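# Brute-force fixed-step reference for the pacemaker timing cycle: marches
# a 0.1 ms grid and, within each tick, processes due triggers and due
# device deadlines in exact-time order. Deadline registers are continuous,
# so pace times should agree with the event-driven engine to within one
# step (the tolerance absorbs same-tick ordering).

oracle_pm_run <- function(settings, trigger_times, amplitude, duration_ms,
                          trigger_channel = "A", dt = 0.1) {
  uri <- 60000 / settings$mtr_bpm
  esc_int <- 60000 / settings$basic_rate_bpm
  eff_vdd <- effective_mode(settings) == "VDD"
  a_thr <- settings$a_sense_mV
  v_thr <- settings$v_sense_mV
  ct <- settings$crosstalk_mV
  pace_t <- numeric(0)
  pace_kind <- character(0)
  last <- NA_real_
  refr <- -Inf
  pend <- NA_real_
  pend_kind <- NA_character_
  escape_dl <- esc_int
  inhibit_next <- FALSE
  tri <- trigger_times[trigger_times <= duration_ms]
  ti <- 1L
  nt <- length(tri)
  nsteps <- ceiling(duration_ms / dt)
  for (k in seq_len(nsteps)) {
    t <- min(k * dt, duration_ms)
    repeat {
      esc_eff <- if (is.na(last)) escape_dl else max(escape_dl, last + uri)
      pace_is_pend <- !is.na(pend) && pend <= esc_eff
      pace_due <- if (pace_is_pend) pend else esc_eff
      trig_due <- if (ti <= nt) tri[ti] else Inf
      if (pace_due > t && trig_due > t) break
      if (pace_due <= t && pace_due <= trig_due) {
        pace_t <- c(pace_t, pace_due)
        pace_kind <- c(pace_kind, if (pace_is_pend) pend_kind else "escape")
        last <- pace_due
        refr <- pace_due + settings$pvarp_ms
        escape_dl <- pace_due + esc_int
        pend <- NA_real_
        pend_kind <- NA_character_
        if (eff_vdd && ct > v_thr) inhibit_next <- TRUE
      } else {
        ts <- trig_due
        ti <- ti + 1L
        if (trigger_channel == "A") {
          if (amplitude > a_thr && ts >= refr) {
            if (inhibit_next) {
              inhibit_next <- FALSE
            } else if (is.na(pend)) {
              tp <- ts + settings$av_delay_ms
              knd <- "triggered"
              if (!is.na(last) && tp < last + uri) {
                tp <- last + uri
                knd <- "deferred"
              }
              pend <- tp
              pend_kind <- knd
            }
          }
        } else if (amplitude > v_thr) {
          if (!is.na(pend)) {
            pend <- NA_real_
            pend_kind <- NA_character_
          } else {
            inhibit_next <- TRUE
          }
        }
      }
    }
  }
  data.frame(time_ms = pace_t, detail = pace_kind, stringsAsFactors = FALSE)
}

# one random engine configuration (uses the session RNG; seed at call site)
random_engine_config <- function() {
  jet <- sample(JET_RATES, 1L)
  s <- default_settings()
  s <- set_parameter(s, "power_on", TRUE)
  s <- set_parameter(s, "mtr_bpm", sample(seq(80, 300, 10), 1L))
  s <- set_parameter(s, "pvarp_ms", sample(seq(0, 300, 25), 1L))
  av <- min(sample(seq(0, 300, 10), 1L),
            max_av_delay(s$mtr_bpm, s$pvarp_ms))
  s <- set_parameter(s, "av_delay_ms", av)
  s <- set_parameter(s, "basic_rate_bpm", sample(seq(60, 250, 10), 1L))
  s <- set_parameter(s, "a_sense_mV", sample(c(0.5, 2, 5, 8, 12), 1L))
  s <- set_parameter(s, "v_sense_mV", sample(c(0.5, 8, 20), 1L))
  list(settings = s, jet = jet,
       amp = sample(c(1, 3, 5, 8, 10), 1L),
       phase = runif(1L, 0, 60000 / jet),
       channel = sample(c("A", "A", "A", "V"), 1L))
}

# compare engine and oracle pace trains for one configuration
compare_engine_oracle <- function(cfg, duration_s = 2.5, dt = 0.1) {
  train <- pacer_input_signal(cfg$jet, cfg$amp, duration_s, cfg$phase)
  log <- pm_run(cfg$settings, train, duration_s * 1000, cfg$channel)
  eng <- log$time_ms[log$kind == "pace"]
  ora <- oracle_pm_run(cfg$settings, train$event_times_ms, cfg$amp,
                       duration_s * 1000, cfg$channel, dt)$time_ms
  list(engine = eng, oracle = ora, log = log,
       agree = length(eng) == length(ora) &&
         (length(eng) == 0L || max(abs(eng - ora)) <= dt + 1e-9))
}
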