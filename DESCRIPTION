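Package: avtsim
Title: Simulation of R-Wave Synchronized Atrial Pacing in Postoperative
    Junctional Ectopic Tachycardia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator of R-wave synchronized atrial (AVT)
    temporary pacing for postoperative junctional ectopic tachycardia (JET).
    Provides a JET electrocardiogram source (narrow QRS, no P wave) with
    selectable rates and monitor-lead derivation, a timing-cycle model of an
    AVT-capable dual-chamber external pacemaker (AV delay, PVARP, maximum
    tracking rate, escape interval, sensing thresholds), the lead-swapped
    wiring rig for closed-loop simulation, atrial-pace to ventricular-sense
    interval analysis with behavioral classification of pacing runs, and a
    scoring engine for a ten-step operator-assessment protocol with canned
    mistake fixtures and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
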