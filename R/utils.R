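stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plateau-aware local minima
#'
#' Finds interior local minima of a numeric vector, treating runs of equal
#' values as a single plateau. A plateau qualifies when both flanking runs
#' hold strictly larger finite values; runs touching `NA` never qualify.
#'
#' @param x numeric vector.
#' @return data.frame with columns `start`, `end` (plateau index range) and
#'   `value`.
#' @keywords internal
#' @noRd
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(start = integer(), end = integer(), value = numeric()))
  r <- rle(x)
  m <- length(r$lengths)
  if (m < 3) return(data.frame(start = integer(), end = integer(), value = numeric()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  keep <- logical(m)
  for (i in 2:(m - 1)) {
    keep[i] <- isTRUE(v[i] < v[i - 1]) && isTRUE(v[i] < v[i + 1])
  }
  data.frame(start = starts[keep], end = ends[keep], value = v[keep])
}

# Sub-sample vertex offset of the parabola through (-1,y1), (0,y2), (1,y3);
# returns 0 when the curvature is numerically flat.
parab_vertex <- function(y1, y2, y3) {
  den <- y1 - 2 * y2 + y3
  if (!is.finite(den) || abs(den) < .Machine$double.eps * (abs(y1) + abs(y2) + abs(y3) + 1)) {
    return(0)
  }
  d <- 0.5 * (y1 - y3) / den
  max(-0.5, min(0.5, d))
}

# Parabolic refinement of a minimum at index i of vector y (1-based).
# Returns the refined fractional index; falls back to i at the edges or on
# non-finite neighbours.
refine_minimum <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  if (!all(is.finite(c(y1, y2, y3)))) return(i)
  i + parab_vertex(y1, y2, y3)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 0

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
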