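#' Extract a kymograph (virtual section) from a stack
#'
#' Reslices the time stack along an analysis line: for every frame, intensity
#' is sampled at evenly spaced points along the line by bilinear
#' interpolation and averaged over `width_px` unit-spaced parallel offsets.
#' Row 1 of the result corresponds to the first endpoint; columns are frames,
#' so wall motion appears as the familiar spike pattern when plotted position
#' vertical x time horizontal.
#'
#' The sampling step is as close to 1 px as divides the line length evenly
#' (`length / ceil(length)`), so both endpoints are sampled exactly and
#' reversing the endpoints flips the rows exactly.
#'
#' @param stack a `movie_stack`.
#' @param line an `analysis_line`. Any sample point that falls outside the
#'   image after width offsetting is an error, not clamped -- silent clamping
#'   would bias wall positions.
#' @return an object of class `kymograph` with fields `matrix`
#'   (positions x frames), `sample_spacing_px`, `frame_interval_s`, `line`.
#' @export
extract_kymograph <- function(stack, line) {
  stopifnot(inherits(stack, "movie_stack"), inherits(line, "analysis_line"))
  d <- dim(stack$data)
  rows <- d[1]; cols <- d[2]; nf <- d[3]
  len <- line_length(line)
  n_pos <- as.integer(ceiling(len)) + 1L
  spacing <- len / (n_pos - 1)
  p0 <- line$endpoints[1, ]; p1 <- line$endpoints[2, ]
  u <- (p1 - p0) / len                      # unit direction (x, y)
  nrm <- c(-u[2], u[1])                     # unit normal
  tt <- seq(0, len, length.out = n_pos)
  w <- line$width_px
  offs <- (seq_len(w) - 1) - (w - 1) / 2

  # all sample coordinates: n_pos x w
  X <- outer(tt, rep(1, w)) * u[1] + p0[1] + outer(rep(1, n_pos), offs) * nrm[1]
  Y <- outer(tt, rep(1, w)) * u[2] + p0[2] + outer(rep(1, n_pos), offs) * nrm[2]
  eps <- 1e-9
  if (any(X < -eps | X > cols - 1 + eps | Y < -eps | Y > rows - 1 + eps)) {
    bad_end <- if (any(X[1, ] < -eps | X[1, ] > cols - 1 + eps |
                       Y[1, ] < -eps | Y[1, ] > rows - 1 + eps)) 1 else 2
    stopf(paste0("line \"%s\" exits the %d x %d frame near endpoint %d ",
                 "(x %.2f, y %.2f) after width offsetting"),
          line$id, rows, cols, bad_end,
          line$endpoints[bad_end, 1], line$endpoints[bad_end, 2])
  }
  X <- pmin(pmax(X, 0), cols - 1); Y <- pmin(pmax(Y, 0), rows - 1)

  x0 <- pmin(floor(X), cols - 2); fx <- X - x0
  y0 <- pmin(floor(Y), rows - 2); fy <- Y - y0
  # linear indices of the four corners in a rows x cols matrix (1-based)
  i11 <- (x0) * rows + y0 + 1
  i21 <- i11 + 1                    # y + 1
  i12 <- i11 + rows                 # x + 1
  i22 <- i12 + 1
  out <- matrix(0, n_pos, nf)
  for (f in seq_len(nf)) {
    fr <- stack$data[, , f]
    # difference form of bilinear interpolation: exact on constant images
    f11 <- fr[i11]
    v <- f11 + fy * (fr[i21] - f11) + fx * (fr[i12] - f11) +
      fx * fy * (fr[i22] - fr[i12] - fr[i21] + f11)
    out[, f] <- if (w == 1) v else rowMeans(matrix(v, n_pos, w))
  }
  structure(list(matrix = out, sample_spacing_px = spacing,
                 frame_interval_s = stack$frame_interval_s, line = line),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph \"%s\": %d positions (%.3f px spacing) x %d frames @ %g s\n",
              x$line$id, nrow(x$matrix), x$sample_spacing_px, ncol(x$matrix),
              x$frame_interval_s))
  invisible(x)
}

#' Automatically place analysis lines on a duct stack
#'
#' Estimates the duct axis from the time-averaged frame: per column, the two
#' deepest dark-band minima give the wall positions and their midpoint the
#' duct center; a straight line fitted to the centers gives the axis. Returns
#' `n_lines` transverse lines perpendicular to the axis at evenly spaced
#' axial stations, plus one longitudinal centerline, each transverse line
#' verified to cross two dark bands.
#'
#' @param stack a `movie_stack` with a roughly axis-aligned duct.
#' @param n_lines number of transverse lines (>= 1).
#' @param width_px averaging width passed to each line.
#' @param margin_frac fraction of the axial extent kept clear at either end
#'   when spacing stations.
#' @return list of `analysis_line` objects: `T1..Tn` transverse, then
#'   `"centerline"` longitudinal.
#' @export
auto_place_lines <- function(stack, n_lines, width_px = 1, margin_frac = 0.12) {
  stopifnot(inherits(stack, "movie_stack"))
  if (!is_count(n_lines) || n_lines < 1) stopf("n_lines must be an integer >= 1")
  M <- apply(stack$data, c(1, 2), mean)
  rows <- nrow(M); cols <- ncol(M)
  noise <- stats::mad(diff(as.vector(M)), na.rm = TRUE) / sqrt(2)
  span <- max(M) - min(M)

  centers <- rep(NA_real_, cols)
  seps <- rep(NA_real_, cols)
  for (c in seq_len(cols)) {
    prof <- M[, c]
    w <- find_two_walls(prof, min_separation = 3)
    if (is.null(w)) next
    depth <- stats::median(prof) - max(prof[round(w)])
    if (depth < max(4 * noise, 0.05 * span)) next
    centers[c] <- mean(w)
    seps[c] <- abs(diff(w))
  }
  ok <- which(!is.na(centers))
  if (length(ok) < max(8, cols * 0.3)) {
    stopf(paste0("no duct-like structure detected (two dark wall bands found in ",
                 "%d/%d columns); place lines manually"), length(ok), cols)
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = ok - 1, y = centers[ok] - 1))
  slope <- stats::coef(fit)[2]; icpt <- stats::coef(fit)[1]
  theta <- atan(slope)                       # axis angle to the column axis
  sep <- stats::median(seps, na.rm = TRUE)
  half <- min(sep / 2 + max(8, 0.4 * sep), (rows - 2) / 2)

  x_lo <- (min(ok) - 1) + margin_frac * (max(ok) - min(ok))
  x_hi <- (max(ok) - 1) - margin_frac * (max(ok) - min(ok))
  stations <- if (n_lines == 1) mean(c(x_lo, x_hi)) else seq(x_lo, x_hi, length.out = n_lines)

  axis_u <- c(cos(theta), sin(theta))
  norm_u <- c(-sin(theta), cos(theta))
  lines <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    x <- stations[i]
    cy <- icpt + slope * x
    p0 <- c(x, cy) - half * norm_u
    p1 <- c(x, cy) + half * norm_u
    l <- analysis_line(sprintf("T%d", i), list(p0, p1), kind = "transverse",
                       width_px = width_px, axial_station_col = x)
    prof <- extract_kymograph(two_frame_stack(M, stack$frame_interval_s), l)$matrix[, 1]
    if (is.null(find_two_walls(prof, min_separation = 3))) {
      stopf("auto-placed transverse line at station col %.1f does not cross two dark bands; place lines manually", x)
    }
    lines[[i]] <- l
  }
  c0 <- c(x_lo, icpt + slope * x_lo)
  c1 <- c(x_hi, icpt + slope * x_hi)
  lines[[n_lines + 1]] <- analysis_line("centerline", list(c0, c1),
                                        kind = "longitudinal", width_px = width_px)
  lines
}

# Minimal 2-frame stack wrapping a single mean image, for line validation.
two_frame_stack <- function(M, dt) {
  movie_stack(array(rep(M, 2), dim = c(dim(M), 2)), frame_interval_s = dt)
}

#' Export a kymograph as TIFF and/or PNG
#'
#' The TIFF stores the raw intensities (16-bit, one page); the PNG renders
#' position vertical x time horizontal with row 1 of the matrix at the top.
#'
#' @param kym a `kymograph`.
#' @param tiff_path,png_path output paths; `NULL` skips that format.
#' @return invisibly, the paths written.
#' @export
write_kymograph <- function(kym, tiff_path = NULL, png_path = NULL) {
  stopifnot(inherits(kym, "kymograph"))
  written <- character()
  if (!is.null(tiff_path)) {
    m <- kym$matrix
    m <- pmin(pmax(m, 0), 1)
    tiff::writeTIFF(m, tiff_path, bits.per.sample = 16L, compression = "none")
    written <- c(written, tiff_path)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = max(480, ncol(kym$matrix)),
                   height = max(160, 2 * nrow(kym$matrix)))
    op <- graphics::par(mar = c(4, 4, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    nt <- ncol(kym$matrix); np <- nrow(kym$matrix)
    graphics::image(x = (seq_len(nt) - 1) * kym$frame_interval_s,
                    y = (seq_len(np) - 1) * kym$sample_spacing_px,
                    z = t(kym$matrix[np:1, , drop = FALSE]),
                    col = grDevices::gray.colors(256, 0, 1),
                    xlab = "time (s)", ylab = "position along line (px)",
                    main = sprintf("kymograph %s", kym$line$id), useRaster = TRUE)
    written <- c(written, png_path)
  }
  invisible(written)
}
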