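test_that("factory defaults match the device", {
  s <- default_settings()
  expect_identical(s$mode, "VDD")
  expect_identical(s$mtr_bpm, 230)
  expect_identical(s$basic_rate_bpm, 210)
  expect_identical(s$pvarp_ms, 200)
  expect_identical(s$av_delay_ms, 50)
  expect_identical(s$a_sense_mV, 8)
  expect_identical(s$v_sense_mV, 8)
  expect_identical(s$v_stim_V, 12)
  expect_false(s$power_on)
})

test_that("AV-delay cap agrees with a brute-force sweep and is monotone", {
  expect_identical(max_av_delay(230, 200), 60)
  expect_identical(max_av_delay(300, 200), 0)
  # independent enumeration of the legal 10 ms dial positions
  brute <- function(mtr, pvarp) {
    d <- seq(0, 300, 10)
    ok <- d[d + pvarp <= 60000 / mtr]
    if (length(ok)) max(ok) else 0
  }
  expect_identical(max_av_delay(220, 100), brute(220, 100))
  expect_identical(brute(220, 100), 170)
  for (mtr in seq(80, 300, 20))
    for (pvarp in seq(0, 400, 50))
      expect_identical(max_av_delay(mtr, pvarp), brute(mtr, pvarp))
  # non-increasing in both arguments
  grid <- expand.grid(mtr = seq(100, 280, 20), pvarp = seq(0, 300, 50))
  caps <- mapply(max_av_delay, grid$mtr, grid$pvarp)
  for (p in unique(grid$pvarp))
    expect_true(all(diff(caps[grid$pvarp == p]) <= 0))
  for (m in unique(grid$mtr))
    expect_true(all(diff(caps[grid$mtr == m]) <= 0))
})

test_that("programming a parameter enforces device constraints", {
  s <- default_settings()
  s1 <- set_parameter(s, "av_delay_ms", 170)
  expect_identical(s1$av_delay_ms, 60)          # clamped under MTR 230/PVARP 200
  expect_true(attr(s1, "clamped_av_delay"))

  s2 <- set_parameter(set_parameter(s, "pvarp_ms", 100), "av_delay_ms", 170)
  expect_identical(s2$av_delay_ms, 160)         # 60000/230 - 100 -> 160

  # shrinking headroom clamps an already-programmed delay
  s3 <- set_parameter(s2, "pvarp_ms", 200)
  expect_identical(s3$av_delay_ms, 60)

  expect_error(set_parameter(s, "mtr_bpm", 0), "programmable range")
  expect_error(set_parameter(s, "sensitivity", 3), "unknown parameter")
  expect_error(set_parameter(s, "av_delay_ms", 55), "10 ms steps")
})

test_that("maximal ventricular insensitivity switches VDD into effective VAT", {
  s <- default_settings()
  expect_identical(effective_mode(s), "VDD")    # v_sense 8: no VAT switch
  expect_identical(effective_mode(set_parameter(s, "v_sense_mV", 20)), "VAT")
  expect_identical(effective_mode(set_parameter(s, "mode", "VVI")), "VVI")
})

test_that("a sensed beat triggers a pace one AV delay later", {
  s <- protocol_settings(200)                   # av_delay 170, effective VAT
  st <- pm_state_new(s)
  out <- step_device(st, s, list(type = "sense", time_ms = 100,
                                 amplitude_mV = 5, channel = "A"))
  out <- step_device(out$state, s, list(type = "tick", time_ms = 400))
  paces <- out$events[out$events$kind == "pace", ]
  expect_identical(paces$time_ms, 270)
  expect_identical(paces$detail, "triggered")
  # refractory and escape bookkeeping after the pace
  expect_identical(out$state$refractory_until_ms, 270 + s$pvarp_ms)
  expect_identical(out$state$escape_deadline_ms, 270 + 60000 / 100)
})

test_that("upper-rate deferral keeps paces at least one MTR interval apart", {
  s <- default_settings()
  s <- set_parameter(s, "power_on", TRUE)
  s <- set_parameter(s, "v_sense_mV", 20)
  s <- set_parameter(s, "mtr_bpm", 180)
  s <- set_parameter(s, "pvarp_ms", 50)
  s <- set_parameter(s, "av_delay_ms", 170)
  s <- set_parameter(s, "a_sense_mV", 2.5)
  s <- set_parameter(s, "basic_rate_bpm", 60)
  train <- pacer_input_signal(200, 5, 10)       # senses 300 ms apart
  log <- pm_run(s, train, 10000)
  gaps <- diff(log$time_ms[log$kind == "pace"])
  expect_true(all(gaps >= 60000 / 180 - 1e-9))
  expect_true(any(log$detail[log$kind == "pace"] == "deferred"))
})

test_that("without sensed triggers the device escapes at the basic rate", {
  s <- set_parameter(default_settings(), "power_on", TRUE)
  s <- set_parameter(s, "v_sense_mV", 20)
  s <- set_parameter(s, "basic_rate_bpm", 100)
  train <- pacer_input_signal(200, 5, 6)        # 5 mV < 8 mV threshold
  log <- pm_run(s, train, 6000)
  paces <- log$time_ms[log$kind == "pace"]
  expect_true(all(log$detail[log$kind == "pace"] == "escape"))
  expect_equal(diff(paces), rep(600, length(paces) - 1), tolerance = 1e-9)
  expect_true(all(log$kind[log$channel == "ventricle"] == "subthreshold"))
})

test_that("the pause function measures the intrinsic signal and halves it", {
  s <- default_settings()
  m <- measure_r_wave(s, pacer_input_signal(200, 5, 2))
  expect_false(m$no_signal)
  expect_identical(m$amplitude_mV, 5)
  expect_identical(m$recommended_a_sense_mV, 2.5)

  none <- measure_r_wave(s, structure(list(event_times_ms = numeric(0),
                                           amplitude_mV = 5),
                                      class = "trigger_train"))
  expect_true(none$no_signal)
  expect_true(is.na(none$amplitude_mV))
})

test_that("event-driven engine agrees with the fixed-step reference", {
  set.seed(42)
  for (i in 1:25) {
    cfg <- random_engine_config()
    cmp <- compare_engine_oracle(cfg)
    expect_true(cmp$agree, label = sprintf(
      "config %d (jet %g, mtr %g, basic %g, pvarp %g, av %g, a_sense %g, v_sense %g, ch %s)",
      i, cfg$jet, cfg$settings$mtr_bpm, cfg$settings$basic_rate_bpm,
      cfg$settings$pvarp_ms, cfg$settings$av_delay_ms,
      cfg$settings$a_sense_mV, cfg$settings$v_sense_mV, cfg$channel))
  }
})

test_that("events cannot run backwards in time", {
  s <- protocol_settings(200)
  st <- pm_state_new(s)
  out <- step_device(st, s, list(type = "sense", time_ms = 500,
                                 amplitude_mV = 5, channel = "A"))
  expect_error(step_device(out$state, s,
                           list(type = "sense", time_ms = 400,
                                amplitude_mV = 5, channel = "A")),
               "precedes")
  expect_error(pm_run(default_settings(), pacer_input_signal(200, 5, 1), 1000),
               "switched off")
})
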