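const_stack <- function(value = 0.7, rows = 20, cols = 30, frames = 4, dt = 1) {
  movie_stack(array(value, dim = c(rows, cols, frames)), frame_interval_s = dt)
}

random_stack <- function(rows = 20, cols = 30, frames = 5, seed = 3) {
  set.seed(seed)
  movie_stack(array(runif(rows * cols * frames), dim = c(rows, cols, frames)),
              frame_interval_s = 1)
}

test_that("kymograph of a constant stack is exactly constant", {
  k <- extract_kymograph(const_stack(), analysis_line("d", list(c(2.3, 1.7), c(27.1, 17.2))))
  expect_true(all(k$matrix == 0.7))
  expect_equal(ncol(k$matrix), 4)
})

test_that("kymograph dimensions follow the line length", {
  len <- sqrt(10^2 + 7^2)
  k <- extract_kymograph(const_stack(), analysis_line("d", list(c(3, 4), c(13, 11))))
  expect_equal(nrow(k$matrix), ceiling(len) + 1)
  expect_equal(k$sample_spacing_px, len / ceiling(len))
})

test_that("extraction is linear in intensity", {
  s <- random_stack()
  l <- analysis_line("d", list(c(1.2, 2.8), c(28, 16.1)), width_px = 3)
  k1 <- extract_kymograph(s, l)$matrix
  s2 <- movie_stack(0.3 * s$data + 0.2, frame_interval_s = 1)
  k2 <- extract_kymograph(s2, l)$matrix
  expect_equal(k2, 0.3 * k1 + 0.2, tolerance = 1e-12)
})

test_that("reversing the endpoints flips the kymograph rows exactly", {
  s <- random_stack()
  a <- extract_kymograph(s, analysis_line("a", list(c(2, 3), c(25, 15))))$matrix
  b <- extract_kymograph(s, analysis_line("b", list(c(25, 15), c(2, 3))))$matrix
  expect_equal(b, a[nrow(a):1, , drop = FALSE], tolerance = 1e-12)
})

test_that("a width-3 line equals the mean of three width-1 offset lines", {
  s <- random_stack()
  base <- analysis_line("w3", list(c(10, 3), c(10, 16)), width_px = 3)
  k3 <- extract_kymograph(s, base)$matrix
  offs <- lapply(c(-1, 0, 1), function(o) {
    extract_kymograph(s, analysis_line("w1", list(c(10 + o, 3), c(10 + o, 16))))$matrix
  })
  expect_equal(k3, (offs[[1]] + offs[[2]] + offs[[3]]) / 3, tolerance = 1e-12)
})

test_that("noise-free simulated columns match the analytic intensity model", {
  p <- tiny_params(duration_s = 10, noise_sd = 0)
  sim <- simulate_movie(p)
  col <- 31
  k <- extract_kymograph(sim$stack, analysis_line("T", list(c(col, 0), c(col, 47))))
  for (f in c(1, 3, 10)) {
    analytic <- ductokym:::sim_frame(p, f - 1)[, col + 1]
    analytic <- round(pmin(pmax(analytic, 0), 1) * 65535) / 65535
    expect_equal(k$matrix[, f], analytic, tolerance = 1e-9)
  }
})

test_that("wall separation oscillates at the contraction frequency", {
  p <- tiny_params(duration_s = 64, noise_sd = 0)
  sim <- simulate_movie(p)
  tr <- trace_diameter(extract_kymograph(sim$stack, vline(31, p)))
  spec <- Mod(stats::fft(tr$diameter_px - mean(tr$diameter_px)))
  k <- which.max(spec[2:32]) + 1           # positive frequencies only
  expect_equal((k - 1) / 64, 1 / p$contraction_interval_s)  # 0.125 Hz period 8 s
})

test_that("lines leaving the frame are rejected, naming the endpoint", {
  s <- const_stack()
  expect_error(extract_kymograph(s, analysis_line("bad", list(c(5, 5), c(5, 25)))),
               "endpoint 2")
  expect_error(extract_kymograph(s, analysis_line("bad", list(c(-2, 5), c(5, 5)))),
               "endpoint 1")
  # in bounds at width 1 but out of bounds once width offsets apply
  expect_error(extract_kymograph(s, analysis_line("bad", list(c(0.2, 3), c(0.2, 15)),
                                                  width_px = 3)),
               "width offsetting")
})

test_that("auto-placed lines are perpendicular to the duct axis", {
  sim <- simulate_movie(tiny_params(duration_s = 20))
  lines <- auto_place_lines(sim$stack, 3)
  expect_length(lines, 4)                     # 3 transverse + centerline
  trans <- Filter(function(l) l$kind == "transverse", lines)
  stations <- vapply(trans, `[[`, 0, "axial_station_col")
  expect_length(unique(stations), 3)
  for (l in trans) {
    d <- l$endpoints[2, ] - l$endpoints[1, ]
    angle <- abs(atan2(d[2], d[1])) * 180 / pi      # true axis is horizontal
    expect_lt(abs(angle - 90), 2)
  }
  expect_equal(Filter(function(l) l$kind == "longitudinal", lines)[[1]]$id, "centerline")
})

test_that("auto-placement on a blank stack errors", {
  expect_error(auto_place_lines(const_stack(rows = 48, cols = 64), 3),
               "no duct-like structure")
})
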