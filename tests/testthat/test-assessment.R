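mk_session <- function(...) session_record(200, list(...))

test_that("the rubric reproduces the reported point assignments", {
  # major mistakes (1 point)
  expect_identical(score_step("RATE", mk_session())$points, 1L)
  expect_identical(
    score_step("RATE", mk_session(list(step = "RATE", value = 210)))$points,
    1L)
  expect_identical(score_step("PVARP", mk_session())$points, 1L)
  expect_identical(score_step("A-SENSE", mk_session())$points, 1L)
  expect_identical(score_step("V-SENSE", mk_session())$points, 1L)
  expect_identical(score_step("MTR", mk_session())$points, 1L)
  # minor mistakes (2 points)
  expect_identical(
    score_step("MTR", mk_session(list(step = "MTR", value = 200)))$points, 2L)
  expect_identical(
    score_step("R-WAVE",
               mk_session(list(step = "R-WAVE", measured = FALSE)))$points, 2L)
  # correct performance (3 points)
  expect_identical(
    score_step("RATE", mk_session(list(step = "RATE", value = 100)))$points,
    3L)
  expect_identical(
    score_step("MTR", mk_session(list(step = "MTR", value = 210)))$points, 3L)
  expect_identical(
    score_step("MTR", mk_session(list(step = "MTR", value = 220)))$points, 3L)
  expect_error(score_step("WIRE", mk_session()), "unknown protocol step")
})

test_that("rubric boundaries behave as documented", {
  rate_pts <- function(v)
    score_step("RATE", mk_session(list(step = "RATE", value = v)))$points
  expect_identical(vapply(c(100, 179, 180, 199, 200, 210), rate_pts, 1L),
                   c(3L, 3L, 2L, 2L, 1L, 1L))

  asense_pts <- function(v)
    score_step("A-SENSE", mk_session(list(step = "A-SENSE", value = v)))$points
  # 50% of the 5 mV signal within 0.1 mV scores 3; sensing values score 2;
  # thresholds at/above the signal score 1
  expect_identical(vapply(c(2.5, 2.45, 4, 1, 5, 8), asense_pts, 1L),
                   c(3L, 3L, 2L, 2L, 1L, 1L))

  wires_pts <- function(swapped, order)
    score_step("WIRES", mk_session(
      list(step = "WIRES", swapped = swapped, order = order)))$points
  expect_identical(wires_pts(TRUE, "ventricular_first"), 3L)
  expect_identical(wires_pts(TRUE, "atrial_first"), 2L)
  expect_identical(wires_pts(FALSE, "ventricular_first"), 1L)

  # AV delay at the device maximum scores 3 even when reached via the clamp
  s <- session_record(200, list(list(step = "MTR", value = 220),
                                list(step = "PVARP", value = 100),
                                list(step = "AV-DLY", value = 300)))
  expect_identical(score_step("AV-DLY", s)$points, 3L)
  s2 <- session_record(200, list(list(step = "MTR", value = 220),
                                 list(step = "PVARP", value = 100),
                                 list(step = "AV-DLY", value = 100)))
  expect_identical(score_step("AV-DLY", s2)$points, 2L)
})

test_that("session scoring totals and simulates the final settings", {
  fx <- fixture_sessions()
  perfect <- score_session(fx$perfect)
  expect_identical(perfect$total, 30L)
  expect_identical(perfect$behavior$label, "synchronized_1to1")
  expect_identical(perfect$final_settings$av_delay_ms, 170)

  empty <- score_session(session_record(200, list()), simulate = FALSE)
  expect_identical(empty$total, 10L)
  expect_true(all(!empty$scores$performed))

  # defaults except ON/VDD/WIRES correct: 8 mV threshold blocks sensing
  minimal <- session_record(200, list(
    list(step = "ON", value = TRUE),
    list(step = "VDD", value = "VDD"),
    list(step = "WIRES", swapped = TRUE, order = "ventricular_first")))
  rep_min <- score_session(minimal)
  expect_false(rep_min$behavior$label == "synchronized_1to1")
})

test_that("scoring is pure and order-insensitive for independent steps", {
  fx <- fixture_sessions()
  r1 <- score_session(fx$mtr_equal, simulate = FALSE)
  r2 <- score_session(fx$mtr_equal, simulate = FALSE)
  expect_identical(r1$scores, r2$scores)

  acts <- fx$perfect$actions
  shuffled <- acts[c(10, 1, 2, 3, 4, 5, 6, 9, 8, 7)]  # keep PVARP before AV-DLY
  expect_identical(
    score_session(session_record(200, shuffled), simulate = FALSE)$scores,
    score_session(fx$perfect, simulate = FALSE)$scores)
})

test_that("each single-mistake fixture loses points exactly where intended", {
  fx <- fixture_sessions()
  pts <- function(nm, step) {
    r <- score_session(fx[[nm]], simulate = FALSE)
    r$scores$points[r$scores$step == step]
  }
  expect_identical(pts("vsense_untouched", "V-SENSE"), 1L)
  expect_identical(pts("mtr_equal", "MTR"), 2L)
  expect_identical(pts("mtr_untouched", "MTR"), 1L)
  expect_identical(pts("pvarp_untouched", "PVARP"), 1L)
  expect_identical(pts("rate_190", "RATE"), 2L)
  expect_identical(pts("rate_untouched", "RATE"), 1L)
  expect_identical(pts("rwave_skipped", "R-WAVE"), 2L)
  expect_identical(pts("asense_untouched", "A-SENSE"), 1L)
  expect_identical(pts("wires_atrial_first", "WIRES"), 2L)
  # every other step in each fixture stays at 3 points
  for (nm in setdiff(names(fx), "perfect")) {
    r <- score_session(fx[[nm]], simulate = FALSE)
    expect_gte(r$total, 28L)
  }
})

test_that("behavioral major mistakes break synchronized pacing in simulation", {
  fx <- fixture_sessions()
  for (nm in c("vsense_untouched", "rate_untouched", "asense_untouched")) {
    r <- score_session(fx[[nm]], sim_duration_s = 10)
    expect_true(any(r$scores$points == 1L), label = nm)
    expect_false(r$behavior$label == "synchronized_1to1", label = nm)
  }
  # straight wiring: scored 1 and no ventriculoatrial synchrony
  straight <- session_record(200, c(
    fixture_sessions()$perfect$actions[1:9],
    list(list(step = "WIRES", swapped = FALSE, order = "ventricular_first"))))
  r <- score_session(straight, sim_duration_s = 10)
  expect_identical(r$scores$points[r$scores$step == "WIRES"], 1L)
  expect_false(r$behavior$label == "synchronized_1to1")
})

test_that("the cohort replay reproduces the reported score distribution", {
  reports <- lapply(cohort_sessions(), score_session, simulate = FALSE)
  tab <- summarize_cohort(reports)
  row <- function(step) unlist(tab[tab$step == step, c("pts3", "pts2", "pts1")],
                               use.names = FALSE)
  expect_identical(row("ON"), c(10L, 0L, 0L))
  expect_identical(row("VDD"), c(10L, 0L, 0L))
  expect_identical(row("V-SENSE"), c(9L, 0L, 1L))
  expect_identical(row("MTR"), c(7L, 2L, 1L))
  expect_identical(row("AV-DLY"), c(5L, 5L, 0L))
  expect_identical(row("PVARP"), c(7L, 0L, 3L))
  expect_identical(row("RATE"), c(3L, 3L, 4L))
  expect_identical(row("R-WAVE"), c(2L, 8L, 0L))
  expect_identical(row("A-SENSE"), c(3L, 5L, 2L))
  expect_identical(row("WIRES"), c(5L, 5L, 0L))

  # a single perfect report lands entirely in the 3-point column
  solo <- summarize_cohort(list(score_session(fixture_sessions()$perfect,
                                              simulate = FALSE)))
  expect_true(all(solo$pts3 == 1L) && all(solo$pts1 == 0L) &&
                all(solo$pts2 == 0L))
  expect_error(summarize_cohort(list()), "no reports")

  md <- cohort_table_markdown(tab)
  expect_identical(length(md), 12L)
  expect_match(md[which(tab$step == "MTR") + 2L], "\\| 1 \\| 2 \\| 7 \\|")
})
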