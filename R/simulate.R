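# Contraction pulse clock. Onsets start at t = 0 and advance by the
# contraction interval of the regime active at the previous onset, so a
# schedule change takes effect at the first onset at or after the change time
# and no pulse is truncated. `pad_before`/`pad_after` extend the clock beyond
# [0, duration) so that stations with a peristaltic lag still see pulses.
sim_onsets <- function(params, pad_before = 0, pad_after = 0) {
  base <- params$contraction_interval_s
  sch <- params$schedule
  interval_at <- function(t) {
    if (nrow(sch) == 0) return(base)
    i <- findInterval(t, sch$time_s)
    if (i == 0) base else sch$new_contraction_interval_s[i]
  }
  onsets <- numeric(0)
  if (pad_before > 0) {
    k <- ceiling(pad_before / base)
    onsets <- seq(-k * base, -base, by = base)
  }
  t <- 0
  end <- params$duration_s + pad_after
  while (t < end) {
    onsets <- c(onsets, t)
    t <- t + interval_at(t)
  }
  onsets
}

# Peristaltic lag of each column (seconds); zero for global contractions.
sim_lag <- function(params, cols) {
  if (is.infinite(params$wave_speed_px_per_s)) return(rep(0, length(cols)))
  (cols - params$wave_origin_col) / params$wave_speed_px_per_s
}

max_abs_lag <- function(params) {
  cols <- params$image_shape[2]
  max(abs(sim_lag(params, c(0, cols - 1))))
}

# Unit raised-cosine pulse train evaluated at local times `tprime` given the
# sorted onset vector: 0.5 * (1 - cos(2*pi*s/w)) for s in [0, w), else 0.
pulse_value <- function(tprime, onsets, width) {
  idx <- findInterval(tprime, onsets)
  s <- tprime - onsets[pmax(idx, 1L)]
  p <- numeric(length(tprime))
  act <- idx >= 1L & s >= 0 & s < width
  p[act] <- 0.5 * (1 - cos(2 * pi * s[act] / width))
  p
}

#' Analytic duct diameter of the simulation model
#'
#' Evaluates the continuous-time diameter `D(c, t) = D0 * (1 - A * p(t -
#' tau(c)))` of the simulated duct at time `t` for the given columns, where
#' `p` is the raised-cosine pulse train and `tau(c)` the peristaltic lag.
#' This is the ground-truth signal the wall-tracking chain is validated
#' against; it is independent of the frame interval.
#'
#' @param params a `sim_params` object.
#' @param t_s time in seconds (scalar).
#' @param cols 0-based column coordinates (defaults to every column).
#' @return numeric vector of diameters in pixels.
#' @export
duct_diameter <- function(params, t_s, cols = seq_len(params$image_shape[2]) - 1) {
  pad <- max_abs_lag(params) + params$pulse_width_s
  onsets <- sim_onsets(params, pad_before = pad, pad_after = pad)
  tau <- sim_lag(params, cols)
  p <- pulse_value(t_s - tau, onsets, params$pulse_width_s)
  params$resting_diameter_px * (1 - params$contraction_amplitude_frac * p)
}

# Noise-free intensity field of one frame (rows x cols), walls + particles.
# `particles` is a data.frame with columns col0, row (initial positions).
sim_frame <- function(params, t_s, onsets = NULL, particles = NULL) {
  rows <- params$image_shape[1]; cols <- params$image_shape[2]
  if (is.null(onsets)) {
    pad <- max_abs_lag(params) + params$pulse_width_s
    onsets <- sim_onsets(params, pad_before = pad, pad_after = pad)
  }
  cc <- seq_len(cols) - 1
  tau <- sim_lag(params, cc)
  p <- pulse_value(t_s - tau, onsets, params$pulse_width_s)
  D <- params$resting_diameter_px * (1 - params$contraction_amplitude_frac * p)
  top <- params$duct_center_row - D / 2
  bot <- params$duct_center_row + D / 2
  rr <- seq_len(rows) - 1
  s2 <- 2 * params$wall_sigma_px^2
  walls <- exp(-outer(rr, top, `-`)^2 / s2) + exp(-outer(rr, bot, `-`)^2 / s2)
  img <- params$background_level - params$wall_depth * walls
  if (!is.null(particles) && nrow(particles) > 0) {
    omega <- 2 * pi / params$flow_osc_period_s
    sp2 <- 2 * params$particle_sigma_px^2
    reach <- ceiling(4 * params$particle_sigma_px)
    for (k in seq_len(nrow(particles))) {
      pc <- (particles$col0[k] + params$flow_net_px_per_s * t_s +
               params$flow_osc_amplitude_px * sin(omega * t_s)) %% cols
      pr <- particles$row[k]
      ci <- ((round(pc) - reach):(round(pc) + reach)) %% cols        # wrapped columns
      dc <- ci - pc
      dc <- dc - cols * round(dc / cols)                              # circular distance
      ri <- max(0, floor(pr - reach)):min(rows - 1, ceiling(pr + reach))
      blob <- params$particle_depth *
        outer(exp(-(ri - pr)^2 / sp2), exp(-dc^2 / sp2))
      img[ri + 1, ci + 1] <- img[ri + 1, ci + 1] - blob
    }
  }
  img
}

#' Ground truth of a simulation without rendering frames
#'
#' Computes the per-station contraction onset times, per-epoch true
#' frequencies and flow/wave parameters implied by a `sim_params` object.
#' [simulate_movie()] attaches exactly this object to its output; computing
#' it alone is cheap and useful for power calculations.
#'
#' @param params a `sim_params` object.
#' @return an object of class `ground_truth` with fields
#'   `event_times_by_station` (list indexed by column label, onset seconds in
#'   `[0, duration)`), `true_frequency_bpm_by_epoch` (data.frame with
#'   `label`, `start_s`, `end_s`, `interval_s`, `bpm`),
#'   `wave_speed_px_per_s`, `net_flow_px_per_s`, `params_echo`, `seed`.
#' @export
ground_truth <- function(params) {
  validate_sim_params(params)
  cols <- params$image_shape[2]
  pad <- max_abs_lag(params) + params$pulse_width_s
  onsets <- sim_onsets(params, pad_before = pad, pad_after = pad)
  cc <- seq_len(cols) - 1
  tau <- sim_lag(params, cc)
  ev <- lapply(seq_along(cc), function(i) {
    t <- onsets + tau[i]
    t[t >= 0 & t < params$duration_s]
  })
  names(ev) <- as.character(cc)
  sch <- params$schedule
  bounds <- c(0, sch$time_s, params$duration_s)
  iv <- c(params$contraction_interval_s, sch$new_contraction_interval_s)
  epochs <- data.frame(
    label = c("Spont", if (nrow(sch)) sch$label),
    start_s = bounds[-length(bounds)],
    end_s = bounds[-1],
    interval_s = iv,
    bpm = 60 / iv,
    stringsAsFactors = FALSE
  )
  structure(list(
    event_times_by_station = ev,
    true_frequency_bpm_by_epoch = epochs,
    wave_speed_px_per_s = params$wave_speed_px_per_s,
    net_flow_px_per_s = params$flow_net_px_per_s,
    params_echo = params,
    seed = params$seed
  ), class = "ground_truth")
}

#' Simulate a transillumination movie of a contracting duct
#'
#' Renders a synthetic time-lapse stack from the analytic duct model: bright
#' background, two dark Gaussian wall bands at `duct_center_row +/- D(c,t)/2`
#' with `D(c, t)` from [duct_diameter()], optional dark luminal particles
#' advected by the prescribed flow, additive Gaussian noise, clipped to
#' `[0, 1]` and quantized to 16-bit levels (so a written TIFF round-trips bit
#' for bit). The same parameters and seed always produce an identical stack
#' and ground truth.
#'
#' @param params a `sim_params` object, e.g. from [preset()].
#' @return list with components `stack` (a `movie_stack`) and `truth`
#'   (a `ground_truth`).
#' @examples
#' sim <- simulate_movie(preset("fig1", image_shape = c(48, 64)))
#' dim(sim$stack$data)
#' @export
simulate_movie <- function(params) {
  validate_sim_params(params)
  truth <- ground_truth(params)
  rows <- params$image_shape[1]; cols <- params$image_shape[2]
  n_frames <- round(params$duration_s / params$frame_interval_s)
  if (n_frames < 2) stopf("simulation must produce at least 2 frames")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  particles <- NULL
  if (params$n_particles > 0) {
    lumen_half <- max(1, params$resting_diameter_px * (1 - params$contraction_amplitude_frac) / 2 -
                        2 * params$particle_sigma_px)
    particles <- data.frame(
      col0 = stats::runif(params$n_particles, 0, cols),
      row = params$duct_center_row + stats::runif(params$n_particles, -1, 1) * lumen_half * 0.6
    )
  }
  pad <- max_abs_lag(params) + params$pulse_width_s
  onsets <- sim_onsets(params, pad_before = pad, pad_after = pad)

  data <- array(0, dim = c(rows, cols, n_frames))
  for (i in seq_len(n_frames)) {
    img <- sim_frame(params, (i - 1) * params$frame_interval_s, onsets, particles)
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(rows * cols, 0, params$noise_sd)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    data[, , i] <- round(img * 65535) / 65535
  }
  stack <- movie_stack(data, frame_interval_s = params$frame_interval_s,
                       origin_label = "ductokym simulation")
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  ne <- length(x$event_times_by_station[[1]])
  cat(sprintf("Simulation ground truth: %d stations, %d onsets at station 0\n",
              length(x$event_times_by_station), ne))
  print(x$true_frequency_bpm_by_epoch)
  invisible(x)
}
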