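test_that("a quiescent duct traces at its resting diameter", {
  p <- tiny_params(duration_s = 30, contraction_amplitude_frac = 0, noise_sd = 0)
  tr <- trace_diameter(extract_kymograph(simulate_movie(p)$stack, vline(31, p)))
  expect_true(all(abs(tr$diameter_px - p$resting_diameter_px) < 0.5))
  expect_equal(tr$gap_frac, 0)
  expect_equal(nrow(detect_contractions(tr)), 0)
})

test_that("trough depth recovers the analytic contraction amplitude", {
  # 7 frames/s so a sample lands essentially on the continuous-time trough
  p <- tiny_params(duration_s = 24, frame_interval_s = 1 / 7, noise_sd = 0)
  tr <- trace_diameter(extract_kymograph(simulate_movie(p)$stack, vline(31, p)))
  depth <- max(tr$baseline_px - tr$diameter_px)
  expect_lt(abs(depth - p$contraction_amplitude_frac * p$resting_diameter_px), 0.5)
})

test_that("the diameter trace is invariant under affine intensity maps", {
  p <- tiny_params(duration_s = 20)
  k <- extract_kymograph(simulate_movie(p)$stack, vline(31, p))
  k2 <- k
  k2$matrix <- 0.5 * k$matrix + 0.1
  expect_equal(trace_diameter(k2)$diameter_px, trace_diameter(k)$diameter_px,
               tolerance = 1e-9)
})

test_that("detected events land on the ground-truth pulse troughs", {
  p <- tiny_params(duration_s = 60)
  sim <- simulate_movie(p)
  ev <- detect_contractions(trace_diameter(extract_kymograph(sim$stack, vline(31, p))))
  truth <- sim$truth$event_times_by_station[["31"]] + p$pulse_width_s / 2
  expect_equal(nrow(ev), length(truth))
  expect_true(all(abs(ev$time_s - truth) <= p$frame_interval_s))
})

test_that("conflicting events within min_interval keep the deeper (earlier on ties)", {
  dip <- function(center, depth, t) depth * exp(-(t - center)^2 / 0.5)
  t <- seq(0, 60, by = 0.25)
  y <- 20 - dip(30, 3, t) - dip(32, 4, t)
  ev <- detect_contractions(make_trace(y, dt = 0.25), min_interval_s = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(round(ev$time_s), 32)          # the deeper of the pair
  expect_gt(ev$prominence_px, 3.5)
  # exactly equal depths: the earlier one wins
  y2 <- rep(20, length(t))
  y2[t == 30] <- 16; y2[t == 32] <- 16
  ev2 <- detect_contractions(make_trace(y2, dt = 0.25), min_interval_s = 3)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$time_s, 30)
  # far enough apart, both survive
  y3 <- 20 - dip(30, 4, t) - dip(40, 3, t)
  expect_equal(nrow(detect_contractions(make_trace(y3, dt = 0.25), min_interval_s = 3)), 2)
})

test_that("short traces are rejected for the requested minimum interval", {
  expect_error(detect_contractions(make_trace(rep(20, 5)), min_interval_s = 3),
               "too short")
})

test_that("frequency arithmetic is exact and half-open", {
  expect_equal(contraction_frequency(seq(0, 232, by = 8) + 1.5, 0, 240), 7.5)
  expect_equal(contraction_frequency(numeric(), 0, 120), 0)
  expect_equal(contraction_frequency(seq(5, 115, by = 10), 0, 120), 6)
  # an event on a window edge counts in exactly one of two abutting windows
  expect_equal(contraction_frequency(60, 0, 60), 0)
  expect_equal(contraction_frequency(60, 60, 120), 1)
  # additivity over any split point
  set.seed(11)
  ev <- sort(runif(40, 0, 100))
  for (b in c(13.2, 50, 77.7)) {
    n_ab <- contraction_frequency(ev, 0, b) * b / 60
    n_bc <- contraction_frequency(ev, b, 100) * (100 - b) / 60
    expect_equal(n_ab + n_bc, contraction_frequency(ev, 0, 100) * 100 / 60)
  }
})

test_that("frequency does not depend on the frame rate on clean input", {
  bpm <- vapply(c(1, 1 / 7), function(dt) {
    p <- tiny_params(duration_s = 64, frame_interval_s = dt, noise_sd = 0)
    ev <- detect_contractions(trace_diameter(extract_kymograph(simulate_movie(p)$stack,
                                                               vline(31, p))))
    contraction_frequency(ev, 0, 64)
  }, 0)
  expect_lt(abs(diff(bpm)), 0.25)
})

test_that("frequency profile is flat across stations, even for peristaltic waves", {
  p <- tiny_params(duration_s = 48, frame_interval_s = 1 / 7,
                   wave_speed_px_per_s = 30)
  sim <- simulate_movie(p)
  prof <- frequency_profile(sim$stack, lapply(c(15, 31, 47), vline, p = p))
  expect_equal(attr(prof, "max_pairwise_diff_bpm"), 0)
  expect_equal(nrow(prof), 3)
  one <- frequency_profile(sim$stack, vline(31, p))
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "max_pairwise_diff_bpm"), 0)
})

test_that("estimated frequency tracks the simulated frequency", {
  for (interval in c(20, 6)) {                 # 3 and 10 beats/min
    for (seed in 1:3) {
      p <- tiny_params(duration_s = 120, contraction_interval_s = interval,
                       noise_sd = 0.02, seed = seed)
      ev <- detect_contractions(trace_diameter(extract_kymograph(
        simulate_movie(p)$stack, vline(31, p))))
      expect_lt(abs(contraction_frequency(ev, 0, 120) - 60 / interval), 0.5)
    }
  }
})
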