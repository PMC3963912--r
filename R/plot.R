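#' Plot a diameter trace with detected contraction events
#'
#' The spike-train view of one transverse section: diameter against time,
#' running-median baseline dashed, detected troughs marked.
#'
#' @param x a `diameter_trace`.
#' @param events optional `contraction_events` for the same line.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.diameter_trace <- function(x, events = NULL, ...) {
  graphics::plot(x$times_s, x$diameter_px, type = "l", col = "grey25",
                 xlab = "time (s)", ylab = "duct diameter (px)",
                 main = sprintf("line %s", x$line_id), ...)
  graphics::lines(x$times_s, x$baseline_px, lty = 2, col = "steelblue")
  if (!is.null(events) && nrow(events) > 0) {
    idx <- round(events$time_s / x$frame_interval_s) + 1
    idx <- pmin(pmax(idx, 1), length(x$diameter_px))
    graphics::points(events$time_s, x$diameter_px[idx], pch = 25,
                     bg = "firebrick", col = "firebrick", cex = 0.8)
  }
  graphics::mtext(sprintf("%d events; noise %.3f px", NROW(events), x$noise_sd_px),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}
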