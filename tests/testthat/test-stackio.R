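test_that("write_stack / read_stack round-trips pixel data bit for bit", {
  sim <- simulate_movie(tiny_params(duration_s = 20))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_identical(back$data, sim$stack$data)
  expect_equal(back$frame_interval_s, sim$stack$frame_interval_s)
  expect_equal(dim(back)[3], 20)
})

test_that("frame interval precedence is flag over sidecar", {
  sim <- simulate_movie(tiny_params(duration_s = 6))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)                      # sidecar says 1 s
  expect_equal(read_stack(path)$frame_interval_s, 1)
  expect_equal(read_stack(path, frame_interval_s = 0.5)$frame_interval_s, 0.5)
})

test_that("a stack without any frame interval source is rejected with advice", {
  sim <- simulate_movie(tiny_params(duration_s = 6))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path, sidecar = FALSE)
  expect_error(read_stack(path), "frame_interval_s=")
})

test_that("single-page TIFFs are rejected as degenerate stacks", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), path, bits.per.sample = 16L)
  expect_error(read_stack(path), ">= 2 frames")
})

test_that("ground truth JSON round-trips its key fields", {
  p <- tiny_params(duration_s = 24, wave_speed_px_per_s = 10)
  truth <- ground_truth(p)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$frame_interval_s, 1)
  expect_equal(back$seed, p$seed)
  expect_equal(back$wave_speed_px_per_s, 10)
  expect_equal(back$events[["0"]], truth$event_times_by_station[["0"]])
  # "global" encodes an infinite wave speed
  g <- ground_truth(tiny_params(duration_s = 24))
  pg <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g, pg)
  expect_equal(read_ground_truth(pg)$wave_speed_px_per_s, "global")
})

test_that("events CSV round-trips, including the empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- data.frame(time_s = c(1.5, 9.5), prominence_px = c(4, 4.2),
                   width_s = c(2, 2.1), line_id = "T1", axial_station_col = 32)
  write_events_csv(ev, path)
  back <- read_events_csv(path)
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$line_id, ev$line_id)

  empty <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev[0, ], empty)
  lines <- readLines(empty)
  expect_length(lines, 1)                                   # header only
  expect_match(lines, "line_id.*time_s.*prominence_px")
  expect_equal(nrow(read_events_csv(empty)), 0)
})

test_that("lines configs round-trip through YAML and read from JSON", {
  l1 <- analysis_line("T1", list(c(10, 2), c(10, 40)), width_px = 3)
  l2 <- analysis_line("mid", list(c(5, 21), c(58, 21)), kind = "longitudinal")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lines_config(list(l1, l2), path)
  back <- read_lines_config(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$endpoints, l1$endpoints)
  expect_equal(back[[1]]$width_px, 3L)
  expect_equal(back[[2]]$kind, "longitudinal")

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(lines = list(
    list(id = "a", kind = "transverse", endpoints = list(c(1, 2), c(1, 30))))),
    jpath, auto_unbox = TRUE)
  jl <- read_lines_config(jpath)
  expect_equal(unname(jl[[1]]$endpoints[2, 2]), 30)
})

test_that("design configs read window settings and additions", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("window_length_s: 120", "post_delay_s: 10", "additions:",
               "  - time_s: 300", "    label: sildenafil 5 uM"), path)
  d <- read_design_config(path)
  expect_s3_class(d, "epoch_design")
  expect_equal(d$schedule$time_s, 300)
  expect_equal(d$window_length_s, 120)
})

test_that("results bundle writer emits the expected files", {
  dir <- withr::local_tempdir()
  ev <- data.frame(time_s = 1, prominence_px = 3, width_s = 2,
                   line_id = "T1", axial_station_col = 10)
  written <- write_results(list(events = ev,
                                frequencies = data.frame(line_id = "T1", bpm = 7.5)),
                           dir)
  expect_true(file.exists(file.path(dir, "events.csv")))
  expect_true(file.exists(file.path(dir, "frequencies.csv")))
  expect_error(write_results(list(), dir), "nothing to write")
})
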