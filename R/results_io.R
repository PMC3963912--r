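#' Write detected events to CSV
#'
#' One row per event: `line_id`, `time_s`, `prominence_px`, `width_s`,
#' `axial_station_col`. Comma-separated, UTF-8, `.` decimal, header always
#' present (an empty event set writes the header only).
#'
#' @param events a `contraction_events` data.frame.
#' @param path output `.csv` path.
#' @return invisibly, `path`.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("line_id", "time_s", "prominence_px", "width_s", "axial_station_col")
  df <- as.data.frame(events)[, cols, drop = FALSE]
  ok <- try(utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stopf("cannot write \"%s\": %s", path, attr(ok, "condition")$message)
  invisible(path)
}

#' Read an events CSV written by [write_events_csv()]
#'
#' @param path `.csv` path.
#' @return a `contraction_events` data.frame.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("line_id", "time_s")
  if (!all(need %in% names(df))) {
    stopf("\"%s\" is not an events CSV (needs columns %s)", path, paste(need, collapse = ", "))
  }
  class(df) <- c("contraction_events", "data.frame")
  df
}

#' Write an analysis results bundle
#'
#' Dispatches each table to its natural format under `dir`: events to CSV,
#' frequency tables to CSV, test results and estimates to JSON, kymographs
#' to TIFF + PNG.
#'
#' @param tables named list; recognized entries are `events`
#'   (`contraction_events`), `frequencies` (data.frame or matrix, beats/min),
#'   `test` (`condition_comparison` or `friedman_test`), `wave`
#'   (`wave_estimate`), `flow` (`flow_estimate`), `kymographs` (list of
#'   `kymograph`s).
#' @param dir output directory, created if needed.
#' @return invisibly, character vector of files written.
#' @export
write_results <- function(tables, dir) {
  if (length(tables) == 0) stopf("nothing to write")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stopf("cannot create output directory \"%s\"", dir)
  }
  written <- character()
  if (!is.null(tables$events)) {
    written <- c(written, write_events_csv(tables$events, file.path(dir, "events.csv")))
  }
  if (!is.null(tables$frequencies)) {
    p <- file.path(dir, "frequencies.csv")
    utils::write.csv(as.data.frame(tables$frequencies), p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(tables$test)) {
    p <- file.path(dir, "stats.json")
    jsonlite::write_json(unclass_deep(tables$test), p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  if (!is.null(tables$wave)) {
    p <- file.path(dir, "wave.json")
    jsonlite::write_json(unclass_deep(tables$wave), p, auto_unbox = TRUE,
                         digits = NA, na = "null")
    written <- c(written, p)
  }
  if (!is.null(tables$flow)) {
    p <- file.path(dir, "flow.json")
    jsonlite::write_json(unclass_deep(tables$flow), p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  if (!is.null(tables$kymographs)) {
    for (k in tables$kymographs) {
      base <- file.path(dir, sprintf("kymo_%s", k$line$id))
      written <- c(written, write_kymograph(k, paste0(base, ".tif"), paste0(base, ".png")))
    }
  }
  invisible(written)
}

# Strip classes recursively so jsonlite serializes plainly; Inf encoded as
# the string "global" where it denotes a non-propagating wave.
unclass_deep <- function(x) {
  if (inherits(x, "wave_estimate") && is.infinite(x$speed_px_per_s)) {
    x$speed_px_per_s <- "global"
  }
  if (is.list(x)) {
    x <- lapply(unclass(x), unclass_deep)
  } else if (is.matrix(x)) {
    x <- as.data.frame(x)
  }
  x
}
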