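# Small, fast simulation defaults for unit tests; the presets keep the full
# validation-scale recordings for the acceptance suite.
tiny_params <- function(...) {
  args <- list(duration_s = 60, image_shape = c(48L, 64L),
               resting_diameter_px = 20, contraction_interval_s = 8,
               contraction_amplitude_frac = 0.2, noise_sd = 0.01, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_params, args)
}

# Vertical transverse line through column x covering both walls.
vline <- function(x, params, id = "T") {
  rows <- params$image_shape[1]
  analysis_line(id, list(c(x, 1), c(x, rows - 2)), kind = "transverse")
}

# Build a diameter_trace directly from a diameter series (for detector tests
# with hand-constructed signals).
make_trace <- function(diam, dt = 1, baseline = NULL, noise_sd = 0.05) {
  n <- length(diam)
  baseline <- baseline %||% rep(stats::median(diam), n)
  structure(list(times_s = (seq_len(n) - 1) * dt, diameter_px = diam,
                 baseline_px = baseline, noise_sd_px = noise_sd,
                 frame_interval_s = dt, line_id = "synthetic",
                 axial_station_col = 0, gap_frac = mean(is.na(diam))),
            class = "diameter_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Friedman oracle: rank sums computed directly from the
# definition (no tie correction terms shared with the implementation).
oracle_friedman_Q <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) R[i, ] <- rank(x[i, ])
  Rj <- colSums(R)
  ties <- 0
  for (i in seq_len(n)) {
    for (v in unique(x[i, ])) {
      t <- sum(x[i, ] == v)
      ties <- ties + t^3 - t
    }
  }
  C <- 1 - ties / (n * (k^3 - k))
  if (C <= 0) return(0)
  (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
}

# Brute-force permutation p for untied k = 3 tables: enumerate all 6^n
# products of within-row rank orderings and count Q* >= Q (inclusive).
oracle_friedman_perm_p <- function(x) {
  stopifnot(ncol(x) == 3)
  n <- nrow(x); k <- 3
  if (any(apply(x, 1, function(r) anyDuplicated(r) > 0))) {
    stop("oracle handles untied tables only")
  }
  perms6 <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                   6, 3, byrow = TRUE)
  choice <- as.matrix(expand.grid(rep(list(1:6), n)))
  R2 <- 0
  Rsum <- matrix(0, nrow(choice), k)
  for (j in seq_len(k)) {
    Rsum[, j] <- rowSums(matrix(perms6[choice, j], nrow(choice), n))
  }
  Qs <- 12 / (n * k * (k + 1)) * rowSums(Rsum^2) - 3 * n * (k + 1)
  mean(Qs >= oracle_friedman_Q(x) - 1e-9)
}
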