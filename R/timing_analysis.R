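# AP-VS interval arithmetic, event-log summaries, behavioral
# classification, and the ladder-style timing diagram.

#' Interval from atrial pace to the next sensed QRS
#'
#' In stable 1:1 AVT pacing the atrial stimulus falls `av_delay_ms` after
#' each sensed QRS, so the gap from that stimulus to the *next* QRS is the
#' cycle length minus the AV delay: `60000 / jet_rate_bpm - av_delay_ms`.
#'
#' @param jet_rate_bpm JET (monitor) heart rate in bpm.
#' @param av_delay_ms Programmed AV delay in ms; must be shorter than the
#'   cycle length.
#' @return AP-VS interval in ms.
#' @examples
#' ap_vs_interval(200, 170)  # 130
#' @export
ap_vs_interval <- function(jet_rate_bpm, av_delay_ms) {
  stopifnot(jet_rate_bpm > 0)
  cl <- 60000 / jet_rate_bpm
  if (av_delay_ms < 0 || av_delay_ms >= cl)
    stop(sprintf("av_delay_ms must lie in [0, %g) at %g bpm", cl, jet_rate_bpm),
         call. = FALSE)
  cl - av_delay_ms
}

pace_times <- function(event_log) {
  event_log$time_ms[event_log$kind == "pace"]
}

sense_times <- function(event_log) {
  event_log$time_ms[event_log$kind == "sense" &
                      event_log$channel == "ventricle"]
}

#' Most frequent inter-pace rate
#'
#' Mode of the inter-pace intervals (0.1 ms bins) converted to bpm.
#'
#' @param event_log An `avt_event_log`.
#' @return Modal pacing rate in bpm, or `NA` with fewer than two paces.
#' @export
modal_pace_rate_bpm <- function(event_log) {
  p <- pace_times(event_log)
  if (length(p) < 2L) return(NA_real_)
  d <- round(diff(p), 1)
  tab <- table(d)
  60000 / as.numeric(names(tab)[which.max(tab)])
}

#' Classify the pacing behavior of a run
#'
#' Labels an event log with one of: `synchronized_1to1` (nearly every pace
#' triggered by a sense and pace rate within tolerance of the JET rate),
#' `two_to_one` (pace rate at half the JET rate with alternating senses
#' dropped into refractoriness), `asynchronous_basic_rate` (modal inter-pace
#' interval at the escape interval with little sense-pace pairing),
#' `no_atrial_pacing` (no paces at all), or `inhibited_or_irregular`.
#'
#' @param event_log An `avt_event_log`.
#' @param jet_rate_bpm JET rate of the run, bpm.
#' @param settings The `pacemaker_settings` used (defaults to the log's
#'   attribute).
#' @param pairing_threshold Minimum triggered-pace fraction for 1:1 and 2:1
#'   labels (default 0.95).
#' @param rate_tol Relative rate tolerance (default 0.02).
#' @return A `behavior_label`: `label` plus an `evidence` list (pace rate,
#'   sense rate, pairing fraction, modal interval, counts).
#' @export
classify_behavior <- function(event_log, jet_rate_bpm,
                              settings = attr(event_log, "settings"),
                              pairing_threshold = 0.95, rate_tol = 0.02) {
  p <- pace_times(event_log)
  s <- sense_times(event_log)
  dur_ms <- attr(event_log, "duration_ms")
  if (is.null(dur_ms)) dur_ms <- max(event_log$time_ms, 0)
  n_drops <- sum(event_log$kind == "refractory_drop")

  evidence <- list(
    n_paces = length(p),
    n_senses = length(s),
    n_refractory_drops = n_drops,
    pace_rate_bpm = if (length(p) >= 2L)
      60000 * (length(p) - 1L) / (max(p) - min(p)) else NA_real_,
    sense_rate_bpm = if (length(s) >= 2L)
      60000 * (length(s) - 1L) / (max(s) - min(s)) else NA_real_,
    pairing_fraction = if (length(p))
      mean(event_log$detail[event_log$kind == "pace"] == "triggered")
    else NA_real_,
    modal_interval_ms = if (length(p) >= 2L)
      60000 / modal_pace_rate_bpm(event_log) else NA_real_
  )

  label <- if (length(p) == 0L) {
    "no_atrial_pacing"
  } else if (length(p) >= 2L &&
             evidence$pairing_fraction >= pairing_threshold &&
             abs(evidence$pace_rate_bpm - jet_rate_bpm) <=
               rate_tol * jet_rate_bpm) {
    "synchronized_1to1"
  } else if (length(p) >= 2L &&
             evidence$pairing_fraction >= pairing_threshold &&
             abs(evidence$pace_rate_bpm - jet_rate_bpm / 2) <=
               rate_tol * jet_rate_bpm / 2 &&
             n_drops >= 0.5 * length(p)) {
    "two_to_one"
  } else if (length(p) >= 2L && !is.null(settings) &&
             abs(evidence$modal_interval_ms -
                   60000 / settings$basic_rate_bpm) <=
               rate_tol * 60000 / settings$basic_rate_bpm &&
             (is.na(evidence$pairing_fraction) ||
                evidence$pairing_fraction < 0.5)) {
    "asynchronous_basic_rate"
  } else {
    "inhibited_or_irregular"
  }
  structure(list(label = label, evidence = evidence),
            class = "behavior_label")
}

#' @export
print.behavior_label <- function(x, ...) {
  e <- x$evidence
  cat(sprintf("<behavior_label> %s\n", x$label))
  cat(sprintf("  paces %d (rate %.1f bpm, pairing %.2f) | senses %d | refractory drops %d\n",
              e$n_paces, e$pace_rate_bpm %||% NA, e$pairing_fraction %||% NA,
              e$n_senses, e$n_refractory_drops))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render an AP-VS ladder diagram
#'
#' Draws the timing relationship the bedside visualizer displays: sensed
#' QRS marks (VS) on the ventricular rung at the JET cycle length, atrial
#' pace marks (AP) one AV delay later on the atrial rung, and the labeled
#' AP to next-VS interval.
#'
#' @param jet_rate_bpm JET rate in bpm.
#' @param av_delay_ms Programmed AV delay in ms.
#' @param file Output path ending in `.svg` or `.png`.
#' @param n_beats Number of beats to draw (default 4).
#' @return `file`, invisibly. The printed interval equals
#'   [ap_vs_interval()] for the same inputs.
#' @export
render_timing_diagram <- function(jet_rate_bpm, av_delay_ms, file,
                                  n_beats = 4) {
  apvs <- ap_vs_interval(jet_rate_bpm, av_delay_ms)
  cl <- 60000 / jet_rate_bpm
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") svg(file, width = 8, height = 3)
  else if (ext == "png") png(file, width = 960, height = 360)
  else stop("file must end in .svg or .png", call. = FALSE)
  on.exit(dev.off())

  vs <- (0:(n_beats - 1)) * cl
  ap <- vs + av_delay_ms
  op <- par(mar = c(3, 4, 3, 1))
  on.exit(par(op), add = TRUE)
  plot.new()
  plot.window(xlim = c(-0.05 * cl, max(vs) + cl * 0.4), ylim = c(0, 3))
  abline(h = c(1, 2), col = "grey70")
  axis(1, at = pretty(c(0, max(vs))), cex.axis = 0.8)
  mtext("time (ms)", side = 1, line = 2, cex = 0.8)
  axis(2, at = c(1, 2), labels = c("V (VS)", "A (AP)"), las = 1, tick = FALSE)
  segments(vs, 0.85, vs, 1.15, lwd = 3)
  segments(ap, 1.85, ap, 2.15, lwd = 3, col = "firebrick")
  segments(vs, 1, ap, 2, lty = 2, col = "grey40")              # AV delay
  n_ap <- head(ap, -1L)
  segments(n_ap, 2, vs[-1L], 1, lty = 3, col = "steelblue")    # AP -> next VS
  arrows(ap[1L], 2.5, vs[2L], 2.5, code = 3, length = 0.08, col = "steelblue")
  text(mean(c(ap[1L], vs[2L])), 2.75,
       sprintf("AP-VS = %g ms", apvs), col = "steelblue", cex = 0.9)
  title(main = sprintf("JET %g bpm (CL %.1f ms), AV delay %g ms",
                       jet_rate_bpm, cl, av_delay_ms), cex.main = 0.95)
  invisible(file)
}
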