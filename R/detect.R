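#' Detect contraction events on a diameter trace
#'
#' Contractions are transient diameter *decreases*: the detector finds local
#' minima of the lightly smoothed trace (3-frame centered mean), measures
#' each trough's prominence against the running-median baseline, keeps those
#' above threshold, and resolves conflicts closer than `min_interval_s` by
#' keeping the deeper event (earlier on ties). Event times are refined to
#' sub-frame precision by a parabola through the trough and its neighbours.
#' Events are never reported inside gap (`NA`) stretches of the trace.
#'
#' @param trace a `diameter_trace`.
#' @param min_prominence_px detection threshold in pixels; default
#'   `max(3 * noise_sd_px, 0.03 * median(baseline_px))`.
#' @param min_interval_s minimum event spacing in seconds; the default 3 s
#'   sits under the shortest physiological period (15 beats/min = 4 s).
#' @return data.frame of class `contraction_events` with columns `time_s`,
#'   `prominence_px`, `width_s` (duration at half prominence), `line_id`,
#'   `axial_station_col`, sorted by time.
#' @export
detect_contractions <- function(trace, min_prominence_px = NULL, min_interval_s = 3) {
  stopifnot(inherits(trace, "diameter_trace"))
  y <- trace$diameter_px
  n <- length(y)
  dt <- trace$frame_interval_s
  if (n * dt <= 2 * min_interval_s) {
    stopf("trace of %.3g s is too short to detect events at min_interval_s = %g s",
          n * dt, min_interval_s)
  }
  if (is.null(min_prominence_px)) {
    min_prominence_px <- max(3 * trace$noise_sd_px,
                             0.03 * stats::median(trace$baseline_px))
  }
  # centered 3-frame mean, shrunk to 2 frames at the trace ends so events in
  # the first/last frames are not lost to the smoothing edge
  sm <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(y[1:2]); sm[n] <- mean(y[(n - 1):n])
  mins <- local_minima(sm)
  cand <- list()
  for (i in seq_len(nrow(mins))) {
    lo <- max(1L, mins$start[i] - 1L); hi <- min(n, mins$end[i] + 1L)
    seg <- y[lo:hi]
    if (all(is.na(seg))) next
    t0 <- lo + which.min(seg) - 1L
    prom <- trace$baseline_px[t0] - y[t0]
    if (!is.finite(prom) || prom < min_prominence_px) next
    tt <- (refine_minimum(y, t0) - 1) * dt
    cand[[length(cand) + 1L]] <- list(idx = t0, time_s = tt, prominence_px = prom,
                                      width_s = half_prominence_width(y, t0, prom, dt))
  }
  if (length(cand) == 0) return(empty_events(trace))
  prom <- vapply(cand, `[[`, 0, "prominence_px")
  tims <- vapply(cand, `[[`, 0, "time_s")
  keep <- logical(length(cand))
  kept_times <- numeric(0)
  for (i in order(-prom, tims)) {        # deeper first, earlier on ties
    if (all(abs(kept_times - tims[i]) >= min_interval_s)) {
      keep[i] <- TRUE
      kept_times <- c(kept_times, tims[i])
    }
  }
  cand <- cand[keep][order(tims[keep])]
  out <- data.frame(
    time_s = vapply(cand, `[[`, 0, "time_s"),
    prominence_px = vapply(cand, `[[`, 0, "prominence_px"),
    width_s = vapply(cand, `[[`, 0, "width_s"),
    line_id = trace$line_id,
    axial_station_col = trace$axial_station_col,
    stringsAsFactors = FALSE
  )
  class(out) <- c("contraction_events", "data.frame")
  out
}

empty_events <- function(trace = NULL) {
  out <- data.frame(time_s = numeric(), prominence_px = numeric(),
                    width_s = numeric(), line_id = character(),
                    axial_station_col = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("contraction_events", "data.frame")
  out
}

# Duration of a trough at half prominence, with linear interpolation of the
# crossings; NA when a crossing is swallowed by a gap or the trace edge.
half_prominence_width <- function(y, t0, prom, dt) {
  level <- y[t0] + prom / 2
  left <- NA_real_; right <- NA_real_
  i <- t0
  while (i > 1) {
    i <- i - 1
    if (is.na(y[i])) return(NA_real_)
    if (y[i] >= level) {
      left <- i + (level - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  i <- t0
  while (i < length(y)) {
    i <- i + 1
    if (is.na(y[i])) return(NA_real_)
    if (y[i] >= level) {
      right <- i - (level - y[i]) / (y[i - 1] - y[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * dt
}

#' Contraction frequency in beats per minute
#'
#' Counts events in the half-open window `[window_start_s, window_end_s)` --
#' half-open so abutting windows never double-count an event -- and converts
#' to beats/min. An empty window gives 0 bpm.
#'
#' @param events a `contraction_events` data.frame or a numeric vector of
#'   event times (seconds).
#' @param window_start_s,window_end_s window bounds, seconds.
#' @return frequency in beats/min.
#' @examples
#' contraction_frequency(seq(0, 232, by = 8) + 1.5, 0, 240)   # 7.5 bpm
#' @export
contraction_frequency <- function(events, window_start_s, window_end_s) {
  t <- if (is.data.frame(events)) events$time_s else as.numeric(events)
  if (window_end_s <= window_start_s) stopf("window_end_s must exceed window_start_s")
  60 * sum(t >= window_start_s & t < window_end_s) / (window_end_s - window_start_s)
}

#' Per-line frequency profile of a stack
#'
#' Runs the full chain (kymograph, diameter trace, spike detection,
#' frequency) for each transverse line over a common window, mirroring the
#' multi-position counting that shows the frequency does not depend on where
#' the virtual section is placed.
#'
#' @param stack a `movie_stack`.
#' @param lines list of `analysis_line`s; longitudinal lines are ignored.
#' @param window numeric `c(start_s, end_s)`; default the full recording.
#' @param ... passed to [detect_contractions()].
#' @return data.frame with one row per line (`line_id`,
#'   `axial_station_col`, `n_events`, `bpm`) and attribute
#'   `max_pairwise_diff_bpm`.
#' @export
frequency_profile <- function(stack, lines, window = NULL, ...) {
  if (inherits(lines, "analysis_line")) lines <- list(lines)
  lines <- Filter(function(l) l$kind == "transverse", lines)
  if (length(lines) < 1) stopf("frequency_profile needs at least one transverse line")
  window <- window %||% c(0, stack_duration(stack))
  res <- lapply(lines, function(l) {
    ev <- detect_contractions(trace_diameter(extract_kymograph(stack, l)), ...)
    inw <- ev$time_s >= window[1] & ev$time_s < window[2]
    data.frame(line_id = l$id, axial_station_col = l$axial_station_col,
               n_events = sum(inw),
               bpm = contraction_frequency(ev, window[1], window[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "max_pairwise_diff_bpm") <- if (nrow(out) > 1) max(stats::dist(out$bpm)) else 0
  attr(out, "window_s") <- window
  out
}
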