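#' Simulation parameters for a synthetic duct movie
#'
#' Bundles and validates the physical and imaging parameters of the
#' transillumination movie simulator: a bright background crossed by two dark
#' duct walls whose separation (the duct diameter) undergoes phasic
#' raised-cosine contractions, optionally propagating along the duct axis as a
#' peristaltic wave, plus dark intraluminal particles with pendular and/or net
#' flow.
#'
#' Coordinates are 0-based with pixel centers at integers, `x` along columns
#' (duct axis) and `y` along rows. The frame captured at index `i` (0-based)
#' represents time `i * frame_interval_s`.
#'
#' @param duration_s recording length in seconds.
#' @param frame_interval_s time between frames in seconds (1 s by default;
#'   use `1/7` for the accelerated capture mode).
#' @param image_shape integer vector `c(rows, cols)` of the frame.
#' @param duct_center_row continuous row coordinate of the duct midline.
#' @param resting_diameter_px wall-to-wall distance at rest (D0), pixels.
#' @param wall_sigma_px Gaussian half-width of each dark wall band, pixels.
#' @param contraction_interval_s seconds between successive contraction
#'   onsets (so frequency is `60 / contraction_interval_s` beats/min).
#' @param contraction_amplitude_frac fractional diameter reduction at pulse
#'   peak, in `[0, 1)`.
#' @param pulse_width_s full duration of one raised-cosine contraction pulse;
#'   must be shorter than every active contraction interval. The default is
#'   3 s, capped at half the contraction interval: phasic contractions stay
#'   brief relative to the cycle even at high rates, and a pulse occupying
#'   most of the cycle would amount to a tonic contraction pattern.
#' @param wave_speed_px_per_s signed peristaltic propagation speed along
#'   increasing column; `Inf` or `"global"` for simultaneous (non-propagating)
#'   contractions.
#' @param wave_origin_col column at which contraction pulses originate.
#' @param n_particles number of dark intraluminal particles.
#' @param flow_net_px_per_s mean luminal advection velocity (signed, px/s).
#' @param flow_osc_amplitude_px amplitude of the sinusoidal pendular particle
#'   displacement, pixels.
#' @param flow_osc_period_s period of the pendular oscillation, seconds.
#' @param particle_sigma_px Gaussian radius of one particle, pixels.
#' @param noise_sd additive Gaussian intensity noise SD (intensity units,
#'   full scale `[0, 1]`).
#' @param background_level,wall_depth,particle_depth intensities of the
#'   bright background and of the dark wall/particle contributions.
#' @param seed integer RNG seed; the same parameters and seed reproduce the
#'   movie bit for bit.
#' @param schedule drug-like regime changes: a data.frame (or list of lists)
#'   with columns `time_s`, `new_contraction_interval_s`, `label`. The pulse
#'   interval switches at the first onset at or after each change time; no
#'   pulse is truncated mid-flight.
#' @return an object of class `sim_params`.
#' @seealso [preset()] for ready-made parameter sets, [simulate_movie()].
#' @export
simulation_params <- function(duration_s = 240,
                              frame_interval_s = 1,
                              image_shape = c(64L, 192L),
                              duct_center_row = (image_shape[1] - 1) / 2,
                              resting_diameter_px = 30,
                              wall_sigma_px = 2,
                              contraction_interval_s = 8,
                              contraction_amplitude_frac = 0.2,
                              pulse_width_s = min(3, contraction_interval_s / 2),
                              wave_speed_px_per_s = Inf,
                              wave_origin_col = 0,
                              n_particles = 0,
                              flow_net_px_per_s = 0,
                              flow_osc_amplitude_px = 0,
                              flow_osc_period_s = 30,
                              particle_sigma_px = 1.5,
                              noise_sd = 0.01,
                              background_level = 0.85,
                              wall_depth = 0.5,
                              particle_depth = 0.35,
                              seed = 42L,
                              schedule = NULL) {
  if (identical(wave_speed_px_per_s, "global")) wave_speed_px_per_s <- Inf
  p <- structure(list(
    duration_s = duration_s,
    frame_interval_s = frame_interval_s,
    image_shape = as.integer(image_shape),
    duct_center_row = duct_center_row,
    resting_diameter_px = resting_diameter_px,
    wall_sigma_px = wall_sigma_px,
    contraction_interval_s = contraction_interval_s,
    contraction_amplitude_frac = contraction_amplitude_frac,
    pulse_width_s = pulse_width_s,
    wave_speed_px_per_s = wave_speed_px_per_s,
    wave_origin_col = wave_origin_col,
    n_particles = as.integer(n_particles),
    flow_net_px_per_s = flow_net_px_per_s,
    flow_osc_amplitude_px = flow_osc_amplitude_px,
    flow_osc_period_s = flow_osc_period_s,
    particle_sigma_px = particle_sigma_px,
    noise_sd = noise_sd,
    background_level = background_level,
    wall_depth = wall_depth,
    particle_depth = particle_depth,
    seed = as.integer(seed),
    schedule = normalize_schedule(schedule)
  ), class = "sim_params")
  validate_sim_params(p)
  p
}

normalize_schedule <- function(schedule) {
  if (is.null(schedule) || (is.data.frame(schedule) && nrow(schedule) == 0)) {
    return(data.frame(time_s = numeric(), new_contraction_interval_s = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(schedule)) {
    schedule <- do.call(rbind, lapply(schedule, function(ch) {
      data.frame(time_s = ch$time_s,
                 new_contraction_interval_s = ch$new_contraction_interval_s,
                 label = as.character(ch$label %||% ""),
                 stringsAsFactors = FALSE)
    }))
  }
  need <- c("time_s", "new_contraction_interval_s", "label")
  if (!all(need %in% names(schedule))) {
    stopf("schedule must have columns: %s", paste(need, collapse = ", "))
  }
  schedule <- schedule[order(schedule$time_s), need, drop = FALSE]
  rownames(schedule) <- NULL
  schedule
}

validate_sim_params <- function(p) {
  if (!is_number(p$duration_s) || p$duration_s <= 0) stopf("duration_s must be > 0")
  if (!is_number(p$frame_interval_s) || p$frame_interval_s <= 0) stopf("frame_interval_s must be > 0")
  if (length(p$image_shape) != 2 || any(p$image_shape < 8)) stopf("image_shape must be c(rows, cols) with both >= 8")
  if (p$contraction_amplitude_frac < 0 || p$contraction_amplitude_frac >= 1) {
    stopf("contraction_amplitude_frac must lie in [0, 1), got %g", p$contraction_amplitude_frac)
  }
  intervals <- c(p$contraction_interval_s, p$schedule$new_contraction_interval_s)
  if (any(intervals <= 0)) stopf("contraction intervals must be > 0")
  if (p$pulse_width_s <= 0 || any(p$pulse_width_s >= intervals)) {
    stopf("pulse_width_s (%g s) must be positive and shorter than every contraction interval (min %g s)",
          p$pulse_width_s, min(intervals))
  }
  rows <- p$image_shape[1]
  if (p$resting_diameter_px + 6 * p$wall_sigma_px >= rows) {
    stopf("duct does not fit the frame: resting_diameter_px + 6*wall_sigma_px = %g >= %d rows",
          p$resting_diameter_px + 6 * p$wall_sigma_px, rows)
  }
  half <- p$resting_diameter_px / 2 + 3 * p$wall_sigma_px
  if (p$duct_center_row - half < 0 || p$duct_center_row + half > rows - 1) {
    stopf("duct walls leave the frame: duct_center_row %g with half-extent %g px outside [0, %d]",
          p$duct_center_row, half, rows - 1)
  }
  if (nrow(p$schedule) > 0) {
    if (any(p$schedule$time_s <= 0 | p$schedule$time_s >= p$duration_s)) {
      stopf("schedule times must lie strictly inside (0, duration_s)")
    }
    if (any(diff(p$schedule$time_s) <= 0)) stopf("schedule times must be strictly increasing")
  }
  if (p$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (p$wave_speed_px_per_s == 0) stopf("wave_speed_px_per_s must be nonzero (use Inf or \"global\" for simultaneous contractions)")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Duct movie simulation parameters\n"))
  cat(sprintf("  %g s at %g s/frame (%d frames), image %d x %d px\n",
              x$duration_s, x$frame_interval_s, round(x$duration_s / x$frame_interval_s),
              x$image_shape[1], x$image_shape[2]))
  cat(sprintf("  diameter %g px, contraction every %g s (%.3g bpm), amplitude %g%%\n",
              x$resting_diameter_px, x$contraction_interval_s,
              60 / x$contraction_interval_s, 100 * x$contraction_amplitude_frac))
  wv <- if (is.infinite(x$wave_speed_px_per_s)) "global" else sprintf("%g px/s", x$wave_speed_px_per_s)
  cat(sprintf("  wave: %s; particles: %d (net %g px/s, pendular %g px / %g s)\n",
              wv, x$n_particles, x$flow_net_px_per_s, x$flow_osc_amplitude_px, x$flow_osc_period_s))
  if (nrow(x$schedule) > 0) {
    for (i in seq_len(nrow(x$schedule))) {
      cat(sprintf("  at %g s: interval -> %g s (%s)\n", x$schedule$time_s[i],
                  x$schedule$new_contraction_interval_s[i], x$schedule$label[i]))
    }
  }
  invisible(x)
}

#' Named simulation presets
#'
#' Fixed, documented parameter sets used throughout the package's validation:
#' \describe{
#'   \item{`fig1`}{240 s at 1 frame/s, global (non-propagating) contractions
#'     every 8.0 s (7.5 beats/min), amplitude 20%, seed 42.}
#'   \item{`peristaltic`}{120 s at 7 frames/s, contraction pulses originating
#'     at the left edge and propagating at 50 px/s.}
#'   \item{`pendular_flow`}{120 s at 1 frame/s, 12 luminal particles with
#'     purely pendular motion (5 px amplitude, 30 s period, zero net drift).}
#'   \item{`net_flow`}{120 s at 1 frame/s, 12 particles drifting at
#'     2 px/s with a small 1 px pendular component.}
#'   \item{`drug_response`}{480 s at 1 frame/s; contraction interval 8.0 s
#'     switching to 20.0 s at t = 300 s (labelled "sildenafil 5 uM"),
#'     emulating a drug that slows spontaneous contractions.}
#' }
#'
#' @param name preset name.
#' @param seed optional seed override.
#' @param ... named `simulation_params()` overrides.
#' @return a `sim_params` object.
#' @examples
#' preset("fig1")$contraction_interval_s       # 8 s -> 7.5 beats/min
#' @export
preset <- function(name, seed = NULL, ...) {
  presets <- list(
    fig1 = list(duration_s = 240, frame_interval_s = 1, contraction_interval_s = 8,
                contraction_amplitude_frac = 0.2, wave_speed_px_per_s = Inf, seed = 42L),
    peristaltic = list(duration_s = 120, frame_interval_s = 1 / 7,
                       contraction_interval_s = 8, contraction_amplitude_frac = 0.2,
                       wave_speed_px_per_s = 50, wave_origin_col = 0, seed = 42L),
    pendular_flow = list(duration_s = 120, frame_interval_s = 1,
                         contraction_interval_s = 8, contraction_amplitude_frac = 0.2,
                         n_particles = 12, flow_net_px_per_s = 0,
                         flow_osc_amplitude_px = 5, flow_osc_period_s = 30, seed = 42L),
    net_flow = list(duration_s = 120, frame_interval_s = 1,
                    contraction_interval_s = 8, contraction_amplitude_frac = 0.2,
                    n_particles = 12, flow_net_px_per_s = 2,
                    flow_osc_amplitude_px = 1, flow_osc_period_s = 10, seed = 42L),
    drug_response = list(duration_s = 480, frame_interval_s = 1,
                         contraction_interval_s = 8, contraction_amplitude_frac = 0.2,
                         seed = 42L,
                         schedule = data.frame(time_s = 300,
                                               new_contraction_interval_s = 20,
                                               label = "sildenafil 5 uM",
                                               stringsAsFactors = FALSE))
  )
  if (!name %in% names(presets)) {
    stopf("unknown preset \"%s\"; available presets: %s", name,
          paste(names(presets), collapse = ", "))
  }
  args <- presets[[name]]
  if (!is.null(seed)) args$seed <- seed
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_params, args)
}
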