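#' Movie stack container
#'
#' A time-lapse image stack: a `rows x cols x frames` numeric array of
#' intensities in `[0, 1]` plus the frame interval. Frame `i` (1-based array
#' slice) was captured at `(i - 1) * frame_interval_s` seconds.
#'
#' @param data numeric array `rows x cols x frames`.
#' @param frame_interval_s frame interval in seconds.
#' @param pixel_size_um optional pixel size in micrometres (geometry is kept
#'   in pixel units when absent).
#' @param origin_label free-text provenance label.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_interval_s, pixel_size_um = NULL,
                        origin_label = "") {
  if (!is.array(data) || length(dim(data)) != 3) {
    stopf("data must be a rows x cols x frames array")
  }
  if (dim(data)[3] < 2) stopf("stack must contain >= 2 frames")
  if (!is_number(frame_interval_s) || frame_interval_s <= 0) {
    stopf("frame_interval_s must be a positive number")
  }
  if (anyNA(data)) stopf("stack contains missing values")
  structure(list(data = data, frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um, origin_label = origin_label),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d frames of %d x %d px, %g s/frame (%.4g s total)\n",
              d[3], d[1], d[2], x$frame_interval_s, d[3] * x$frame_interval_s))
  if (nzchar(x$origin_label)) cat(" origin:", x$origin_label, "\n")
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

stack_duration <- function(stack) n_frames(stack) * stack$frame_interval_s

stack_sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a movie stack as multi-page TIFF
#'
#' One 16-bit grayscale page per frame, uncompressed, intensities in
#' `[0, 1]`. The frame interval is stored in a JSON sidecar next to the file
#' (`<stem>.json`), so a later [read_stack()] does not need to be told.
#'
#' @param stack a `movie_stack`.
#' @param path output file path (`.tif`).
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return invisibly, `path`.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "movie_stack"))
  frames <- lapply(seq_len(n_frames(stack)), function(i) stack$data[, , i])
  ok <- try(tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                            compression = "none", reduce = TRUE), silent = TRUE)
  if (inherits(ok, "try-error")) stopf("cannot write TIFF to \"%s\": %s", path, attr(ok, "condition")$message)
  if (sidecar) {
    meta <- list(frame_interval_s = stack$frame_interval_s,
                 origin_label = stack$origin_label)
    if (!is.null(stack$pixel_size_um)) meta$pixel_size_um <- stack$pixel_size_um
    jsonlite::write_json(meta, stack_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a movie stack from a multi-page TIFF
#'
#' Every downstream quantity has units of beats/min, so the frame interval is
#' never guessed: it is taken, in order of precedence, from the
#' `frame_interval_s` argument, from the JSON sidecar (`<stem>.json`), or
#' from a `frame_interval_s=<x>` entry in the TIFF description tag. If none
#' is available the reader stops and instructs the caller to supply the
#' argument (or `--frame-interval` on the command line).
#'
#' @param path path to a multi-page TIFF.
#' @param frame_interval_s optional frame interval override, seconds.
#' @return a `movie_stack`.
#' @export
read_stack <- function(path, frame_interval_s = NULL) {
  if (!file.exists(path)) stopf("no such file: \"%s\"", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stopf("stack must contain >= 2 frames (\"%s\" has %d page)", path, length(pages))
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) {
    stopf("mixed frame shapes in \"%s\": %s", path,
          paste(vapply(dims, function(d) paste(d, collapse = "x"), ""), collapse = ", "))
  }
  if (length(dims[[1]]) != 2) {
    stopf("\"%s\" is not grayscale (page dimensions %s); convert to single-channel first",
          path, paste(dims[[1]], collapse = "x"))
  }
  dt <- frame_interval_s
  if (is.null(dt)) {
    sc <- stack_sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      dt <- meta$frame_interval_s
    }
  }
  if (is.null(dt)) {
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc)) {
      m <- regmatches(desc, regexec("frame_interval_s=([0-9.eE+-]+)", desc))[[1]]
      if (length(m) == 2) dt <- as.numeric(m[2])
    }
  }
  if (is.null(dt) || !is_number(dt) || dt <= 0) {
    stopf(paste0("frame interval for \"%s\" not found in sidecar or TIFF metadata; ",
                 "pass frame_interval_s= (CLI: --frame-interval)"), path)
  }
  data <- array(0, dim = c(dims[[1]], length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  movie_stack(data, frame_interval_s = dt, origin_label = path)
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$params_echo
  p$schedule <- if (nrow(p$schedule)) p$schedule else NULL
  out <- list(
    frame_interval_s = p$frame_interval_s,
    seed = truth$seed,
    wave_speed_px_per_s = if (is.infinite(truth$wave_speed_px_per_s)) "global" else truth$wave_speed_px_per_s,
    net_flow_px_per_s = truth$net_flow_px_per_s,
    true_frequency_bpm_by_epoch = truth$true_frequency_bpm_by_epoch,
    params = unclass(p),
    events = truth$event_times_by_station
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read simulation ground truth written by [write_ground_truth()]
#'
#' @param path `.json` path.
#' @return a list mirroring the written structure (parameters are returned as
#'   a plain list, not re-validated).
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
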