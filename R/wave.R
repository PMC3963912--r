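#' Estimate peristaltic wave propagation from events at several stations
#'
#' Contraction events detected at three or more axial stations are matched by
#' rank (k-th event with k-th event) after reconciling counts: stations whose
#' event count deviates from the modal count are excluded. Event times are
#' then regressed on axial station (pooled over events, each event centered),
#' giving the latency slope in s/px; the wave speed is its reciprocal, signed
#' along increasing column.
#'
#' Classification: `"global"` when the fitted lag across the station span is
#' below the resolvability bound (half a frame interval over the span),
#' `"propagating"` when the latency fit is coherent (`r_squared >= 0.8`),
#' otherwise `"incoherent"`. When the total lag across the span is under one
#' frame interval, the result carries a note recommending capture at a finer
#' time resolution (e.g. 7 frames/s).
#'
#' @param events_by_station either a `contraction_events` data.frame covering
#'   several stations (split on `axial_station_col`) or a named list mapping
#'   station column to a numeric vector of event times.
#' @param frame_interval_s frame interval of the source movie, seconds.
#' @return object of class `wave_estimate`: `speed_px_per_s`,
#'   `latency_slope_s_per_px`, `latency_slope_se`, `r_squared`,
#'   `classification`, `stations_used`, `n_events`, `note`.
#' @export
estimate_wave <- function(events_by_station, frame_interval_s) {
  ev <- normalize_station_events(events_by_station)
  if (length(ev) < 3) {
    stopf("wave estimation needs >= 3 stations with events, got %d", length(ev))
  }
  counts <- vapply(ev, length, 0L)
  tab <- table(counts[counts > 0])
  if (length(tab) == 0) stopf("no events at any station")
  modal <- as.integer(names(tab)[which.max(tab)])
  usable <- counts == modal
  if (sum(usable) < 3) {
    stopf("fewer than 3 stations share a common event count (counts: %s)",
          paste(sprintf("%s:%d", names(ev), counts), collapse = ", "))
  }
  ev <- ev[usable]
  x <- as.numeric(names(ev))
  tm <- do.call(cbind, ev)                        # events x stations matrix
  xc <- x - mean(x)
  yy <- as.vector(t(sweep(tm, 1, rowMeans(tm)))) # event-major, stations fastest
  xx <- rep(xc, nrow(tm))
  sxx <- sum(xx^2)
  slope <- sum(xx * yy) / sxx
  res <- yy - slope * xx
  dfree <- length(yy) - nrow(tm) - 1              # per-event centering costs one df each
  se <- if (dfree > 0) sqrt(sum(res^2) / dfree / sxx) else 0
  tss <- sum(yy^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  span <- diff(range(x))
  lag_across <- abs(slope) * span
  classification <- if (lag_across < frame_interval_s / 2) {
    "global"
  } else if (r2 >= 0.8) {
    "propagating"
  } else {
    "incoherent"
  }
  note <- if (classification != "global" && lag_across < frame_interval_s) {
    sprintf(paste0("fitted lag across the line span (%.3g s) is below one frame ",
                   "interval (%g s); capture at a finer time resolution ",
                   "(e.g. 7 frames/s) to resolve propagation"),
            lag_across, frame_interval_s)
  } else {
    NA_character_
  }
  structure(list(
    speed_px_per_s = if (classification == "global" || slope == 0) Inf else 1 / slope,
    latency_slope_s_per_px = slope,
    latency_slope_se = se,
    r_squared = max(0, min(1, r2)),
    classification = classification,
    stations_used = x,
    n_events = nrow(tm),
    note = note
  ), class = "wave_estimate")
}

normalize_station_events <- function(events_by_station) {
  if (is.data.frame(events_by_station)) {
    sp <- split(events_by_station$time_s, events_by_station$axial_station_col)
    ev <- lapply(sp, sort)
  } else {
    ev <- lapply(events_by_station, sort)
    if (is.null(names(ev)) || any(!nzchar(names(ev)))) {
      stopf("events_by_station list must be named by axial station column")
    }
  }
  ev[order(as.numeric(names(ev)))]
}

#' @export
print.wave_estimate <- function(x, ...) {
  sp <- if (is.infinite(x$speed_px_per_s)) "global (no resolvable lag)"
        else sprintf("%.3g px/s", x$speed_px_per_s)
  cat(sprintf("wave_estimate: %s [%s]\n", sp, x$classification))
  cat(sprintf("  latency slope %.4g +/- %.2g s/px, r^2 = %.3f, %d events x %d stations\n",
              x$latency_slope_s_per_px, x$latency_slope_se, x$r_squared,
              x$n_events, length(x$stations_used)))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
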