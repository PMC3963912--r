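# Locate the two deepest separable intensity minima of a profile (the dark
# wall bands). Returns refined fractional positions (1-based sample index) or
# NULL when two separable minima cannot be found.
find_two_walls <- function(prof, min_separation = 3) {
  mins <- local_minima(prof)
  if (nrow(mins) < 2) return(NULL)
  # representative raw index of each plateau: earliest deepest sample
  idx <- mapply(function(s, e) s + which.min(prof[s:e]) - 1L, mins$start, mins$end)
  ord <- order(mins$value, idx)                     # deepest first, ties earlier
  i1 <- idx[ord[1]]
  rest <- ord[-1][abs(idx[ord[-1]] - i1) >= min_separation]
  if (length(rest) == 0) return(NULL)
  i2 <- idx[rest[1]]
  sort(c(refine_minimum(prof, i1), refine_minimum(prof, i2)))
}

#' Trace the duct diameter from a transverse kymograph
#'
#' For every time column the two deepest intensity minima (the wall bands)
#' are located with sub-pixel parabolic refinement; the diameter is their
#' distance along the line. Columns where two separable walls are not found
#' are marked as gaps (`NA`). The baseline is a centered running median and
#' the residual noise a scaled MAD of the detrended trace, both feeding the
#' default detection threshold of [detect_contractions()].
#'
#' Wall localization uses only intensity ordering (argmin plus a parabola
#' through the neighbours), so the trace is invariant under monotone affine
#' intensity maps.
#'
#' @param kym a `kymograph` from a transverse line crossing both walls.
#' @param baseline_window_s width of the running-median baseline window,
#'   seconds (default 60, well above 5x any physiological pulse width).
#' @param min_separation_px minimum wall separation, pixels.
#' @param max_gap_frac maximum tolerated fraction of gap columns before the
#'   trace is rejected as untrackable.
#' @return an object of class `diameter_trace` with fields `times_s`,
#'   `diameter_px` (`NA` at gaps), `baseline_px`, `noise_sd_px`,
#'   `frame_interval_s`, `line_id`, `axial_station_col`, `gap_frac`.
#' @export
trace_diameter <- function(kym, baseline_window_s = 60, min_separation_px = 3,
                           max_gap_frac = 0.25) {
  stopifnot(inherits(kym, "kymograph"))
  if (kym$line$kind != "transverse") {
    stopf("diameter tracing needs a transverse line, got \"%s\" (line \"%s\")",
          kym$line$kind, kym$line$id)
  }
  nf <- ncol(kym$matrix)
  spacing <- kym$sample_spacing_px
  diam <- rep(NA_real_, nf)
  min_sep_samples <- max(2, round(min_separation_px / spacing))
  for (j in seq_len(nf)) {
    w <- find_two_walls(kym$matrix[, j], min_separation = min_sep_samples)
    if (!is.null(w)) diam[j] <- (w[2] - w[1]) * spacing
  }
  gap_frac <- mean(is.na(diam))
  if (gap_frac > max_gap_frac) {
    stopf("walls not trackable on line \"%s\": %.0f%% of frames lack two separable wall minima",
          kym$line$id, 100 * gap_frac)
  }
  dt <- kym$frame_interval_s
  filled <- diam
  if (anyNA(filled)) {
    filled <- stats::approx(seq_len(nf), diam, xout = seq_len(nf), rule = 2)$y
  }
  k <- round(baseline_window_s / dt)
  k <- min(k, nf)
  if (k %% 2 == 0) k <- k - 1
  # endrule "constant" holds the first/last full-window median at the edges;
  # the shrinking-window alternative lets the baseline collapse onto a trough
  # that sits in the first frames and would mask it
  baseline <- if (k >= 3) as.numeric(stats::runmed(filled, k, endrule = "constant")) else filled
  noise_sd <- stats::mad(diam - baseline, na.rm = TRUE)
  structure(list(times_s = (seq_len(nf) - 1) * dt,
                 diameter_px = diam,
                 baseline_px = baseline,
                 noise_sd_px = noise_sd,
                 frame_interval_s = dt,
                 line_id = kym$line$id,
                 axial_station_col = kym$line$axial_station_col,
                 gap_frac = gap_frac),
            class = "diameter_trace")
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf("diameter_trace \"%s\": %d frames @ %g s, median %.2f px, noise %.3f px, %.1f%% gaps\n",
              x$line_id, length(x$diameter_px), x$frame_interval_s,
              stats::median(x$baseline_px), x$noise_sd_px, 100 * x$gap_frac))
  invisible(x)
}
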