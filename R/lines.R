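#' Analysis line for kymograph extraction
#'
#' Defines the "virtual section" along which a stack is resliced into a
#' kymograph. Coordinates are 0-based continuous `(x = col, y = row)` with
#' pixel centers at integers. A `transverse` line is meant to cross both duct
#' walls (this is validated when the diameter is traced); a `longitudinal`
#' line runs along the lumen and feeds flow estimation.
#'
#' @param id short label.
#' @param endpoints 2x2 numeric matrix, rows = the two endpoints, columns =
#'   `(x, y)`; also accepts `list(c(x1, y1), c(x2, y2))`.
#' @param kind `"transverse"` or `"longitudinal"`.
#' @param width_px averaging width perpendicular to the line, integer >= 1.
#'   The kymograph averages `width_px` parallel lines at unit-spaced offsets
#'   centered on the line.
#' @param axial_station_col representative 0-based column of the line (for
#'   ordering transverse stations along the duct axis); defaults to the mean
#'   x of the endpoints.
#' @return an object of class `analysis_line`.
#' @export
analysis_line <- function(id, endpoints, kind = c("transverse", "longitudinal"),
                          width_px = 1, axial_station_col = NULL) {
  kind <- match.arg(kind)
  if (is.list(endpoints)) endpoints <- rbind(endpoints[[1]], endpoints[[2]])
  endpoints <- matrix(as.numeric(endpoints), 2, 2)
  colnames(endpoints) <- c("x", "y")
  if (all(endpoints[1, ] == endpoints[2, ])) stopf("line \"%s\": endpoints must be distinct", id)
  if (!is_count(width_px) || width_px < 1) stopf("line \"%s\": width_px must be an integer >= 1", id)
  structure(list(id = as.character(id), kind = kind, endpoints = endpoints,
                 width_px = as.integer(width_px),
                 axial_station_col = axial_station_col %||% mean(endpoints[, "x"])),
            class = "analysis_line")
}

#' @export
print.analysis_line <- function(x, ...) {
  cat(sprintf("analysis_line \"%s\" (%s): (%.1f, %.1f) -> (%.1f, %.1f), width %d px, station col %.1f\n",
              x$id, x$kind, x$endpoints[1, 1], x$endpoints[1, 2],
              x$endpoints[2, 1], x$endpoints[2, 2], x$width_px, x$axial_station_col))
  invisible(x)
}

line_length <- function(line) sqrt(sum((line$endpoints[2, ] - line$endpoints[1, ])^2))

#' Read analysis lines from a YAML or JSON config
#'
#' The file holds a top-level `lines:` list; each entry has keys `id`,
#' `kind`, `endpoints` (`[[x1, y1], [x2, y2]]`), and optional `width_px`,
#' `axial_station_col`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list of `analysis_line` objects.
#' @export
read_lines_config <- function(path) {
  cfg <- read_config_file(path)
  entries <- cfg$lines %||% cfg
  if (length(entries) == 0) stopf("no lines found in \"%s\"", path)
  lapply(entries, function(e) {
    ep <- e$endpoints
    if (is.matrix(ep)) ep <- list(ep[1, ], ep[2, ])  # json simplification
    analysis_line(id = e$id, kind = e$kind %||% "transverse",
                  endpoints = list(as.numeric(unlist(ep[[1]])), as.numeric(unlist(ep[[2]]))),
                  width_px = e$width_px %||% 1,
                  axial_station_col = e$axial_station_col)
  })
}

#' Write analysis lines to YAML
#'
#' @param lines list of `analysis_line` objects.
#' @param path output `.yaml` path.
#' @return invisibly, `path`.
#' @export
write_lines_config <- function(lines, path) {
  if (inherits(lines, "analysis_line")) lines <- list(lines)
  out <- list(lines = lapply(lines, function(l) {
    list(id = l$id, kind = l$kind,
         endpoints = list(as.numeric(l$endpoints[1, ]), as.numeric(l$endpoints[2, ])),
         width_px = l$width_px, axial_station_col = l$axial_station_col)
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stopf("no such file: \"%s\"", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stopf("config \"%s\" must be YAML or JSON", path)
  }
}

#' Drug addition schedule
#'
#' Ordered drug additions driving the paired epoch statistics. Times must be
#' strictly increasing; whether the windows around each addition fit the
#' recording is checked by [epoch_frequencies()], which knows the recording
#' duration.
#'
#' @param time_s addition times, seconds.
#' @param label one label per addition (e.g. `"SNP 100 uM"`).
#' @return data.frame of class `drug_schedule` with columns `time_s`, `label`.
#' @export
drug_schedule <- function(time_s, label) {
  if (length(time_s) != length(label)) stopf("time_s and label lengths differ")
  if (length(time_s) == 0) stopf("schedule needs at least one addition")
  if (any(diff(time_s) <= 0)) stopf("schedule times must be strictly increasing")
  structure(data.frame(time_s = as.numeric(time_s), label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("drug_schedule", "data.frame"))
}

#' Read an epoch design (schedule plus window settings) from YAML/JSON
#'
#' Keys: `window_length_s` (default 120), `post_delay_s` (default 10) and
#' `additions:` a list of `{time_s, label}` entries.
#'
#' @param path config file path.
#' @return an `epoch_design` object.
#' @export
read_design_config <- function(path) {
  cfg <- read_config_file(path)
  adds <- cfg$additions
  if (length(adds) == 0) stopf("no additions found in \"%s\"", path)
  sched <- drug_schedule(vapply(adds, function(a) as.numeric(a$time_s), 0),
                         vapply(adds, function(a) as.character(a$label), ""))
  epoch_design(sched,
               window_length_s = cfg$window_length_s %||% 120,
               post_delay_s = cfg$post_delay_s %||% 10)
}
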