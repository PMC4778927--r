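# avtsim

A software bench model of **R-wave synchronized atrial (AVT) pacing** for
postoperative **junctional ectopic tachycardia (JET)** — written for
pediatric cardiologists, intensive-care educators and device-minded
engineers who want to simulate, visualize and score the technique without
a physical rig.

JET is a narrow-complex tachycardia from the bundle of His: the ventricles
run at or above the atrial rate, P waves disappear, and atrioventricular
synchrony is lost. AVT pacing restores synchrony at the *same* heart rate
by deliberately swapping the temporary pacing wires at an external
dual-chamber pacemaker: the device senses each QRS on its atrial channel
and stimulates the atria one AV delay later,

```
AP–VS interval = 60000 / JET rate − AV delay   [ms]
```

so each atrial beat lands just before the next QRS. The setup is
unforgiving: the AV delay is capped by the device at the largest 10 ms
multiple `d` with `d + PVARP ≤ 60000 / MTR`, a basic (escape) rate above
the JET rate takes over and paces asynchronously, a sensitive ventricular
channel keeps the device out of triggered (VAT) behavior, and an untouched
8 mV atrial threshold never sees the ~5 mV intrinsic signal.

The package provides:

* a JET ECG source (sum-of-Gaussians beat, no P wave, 130–240 bpm in 10 bpm
  steps, Einthoven lead derivation, 159 Hz two-section low-pass);
* the programmable pacemaker and its full timing cycle (sensing thresholds,
  AV delay, PVARP, upper-rate deferral, escape pacing, crosstalk
  self-inhibition in effective VDD);
* the swapped-lead rig and deterministic closed-loop simulation;
* AP–VS timing analysis, behavioral classification of runs, and an SVG/PNG
  ladder diagram;
* a scoring engine for the ten-step operator protocol, with canned
  mistake fixtures, a ten-operator cohort replay, and cohort summaries.

## Worked example

```r
library(avtsim)

# the device fresh out of the box
s <- default_settings()
max_av_delay(s$mtr_bpm, s$pvarp_ms)
#> [1] 60
s <- set_parameter(s, "av_delay_ms", 170)   # dial past the cap...
s$av_delay_ms                               # ...the device stops at it
#> [1] 60

# program it per protocol for a 200 bpm JET, but forget the basic rate
s <- set_parameter(s, "power_on", TRUE)
s <- set_parameter(s, "v_sense_mV", 20)     # maximal insensitivity -> VAT
s <- set_parameter(s, "mtr_bpm", 220)
s <- set_parameter(s, "pvarp_ms", 100)
s <- set_parameter(s, "av_delay_ms", 170)   # now the cap allows it
s <- set_parameter(s, "a_sense_mV", 2.5)    # 50% of the 5 mV signal

log <- run_simulation(s, connect_wires(), jet_rate_bpm = 200, duration_s = 60)
round(modal_pace_rate_bpm(log))
#> [1] 210
classify_behavior(log, 200, s)$label
#> [1] "asynchronous_basic_rate"
```

The forgotten basic rate (factory 210 bpm) beats the 200 bpm JET to every
cycle: the device stimulates the atria at 210 bpm with no ventriculoatrial
synchrony. Fixing it (`set_parameter(s, "basic_rate_bpm", 100)`) yields
`synchronized_1to1` with one pace per beat and a measured AP–VS gap of
`ap_vs_interval(200, 170)` = 130 ms.

Scoring an operator session:

```r
rep <- score_session(fixture_sessions()$rate_untouched)
rep$total
#> [1] 28
rep$behavior$label
#> [1] "asynchronous_basic_rate"

summarize_cohort(lapply(cohort_sessions(), score_session, simulate = FALSE))
#>       step pts1 pts2 pts3
#> 1       ON    0    0   10
#> ...
#> 4      MTR    1    2    7
#> 7     RATE    4    3    3
#> ...
```

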