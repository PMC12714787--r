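#' Wrapped toroidal grid
#'
#' Defines the notional space on which agents live: an integer grid whose
#' opposite edges are identified, so distances wrap around both axes. The
#' canonical space is 315 x 315, giving 99,225 grid positions and a maximum
#' pairwise distance of sqrt(2 * 157^2), approximately 222.
#'
#' @param width Integer number of grid cells along x (>= 2).
#' @param height Integer number of grid cells along y (>= 2).
#' @return An object of class `torus_space` with fields `width`, `height`.
#' @examples
#' sp <- torus_space(315, 315)
#' sp$width * sp$height  # 99225 grid positions
#' @export
torus_space <- function(width = 315L, height = 315L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 2L || height < 2L) {
    stop("torus_space: width and height must both be integers >= 2", call. = FALSE)
  }
  structure(list(width = width, height = height), class = "torus_space")
}

#' @export
print.torus_space <- function(x, ...) {
  cat(sprintf("<torus_space %d x %d (%d cells)>\n",
              x$width, x$height, x$width * x$height))
  invisible(x)
}

#' Per-axis wrapped difference
#'
#' min(|d|, L - |d|) for axis length L; vectorized over `d`.
#' @noRd
wrap_diff <- function(d, len) {
  d <- abs(d)
  pmin(d, len - d)
}

#' Torus (wrapped Euclidean) distance
#'
#' Euclidean distance between grid positions where each axis difference wraps:
#' the per-axis displacement is `min(|dx|, L - |dx|)` for axis length `L`.
#' Vectorized over coordinate vectors. With `distance_mode =
#' "euclidean_truncated"` the real-valued distance is truncated (floored) to an
#' integer, a replication mode for implementations that worked in integer
#' distances; the default returns the exact real value.
#'
#' @param x1,y1 Coordinates of the first point(s), integers in `[0, width)` /
#'   `[0, height)`.
#' @param x2,y2 Coordinates of the second point(s).
#' @param space A [torus_space()].
#' @param distance_mode `"euclidean_real"` (default) or `"euclidean_truncated"`.
#' @return Nonnegative numeric vector of distances.
#' @examples
#' sp <- torus_space(315, 315)
#' torus_distance(0, 0, 314, 0, sp)      # 1: wraps around
#' torus_distance(0, 0, 157, 157, sp)    # ~222.03, the maximum attainable
#' @export
torus_distance <- function(x1, y1, x2, y2, space,
                           distance_mode = c("euclidean_real", "euclidean_truncated")) {
  distance_mode <- match.arg(distance_mode)
  dx <- wrap_diff(x1 - x2, space$width)
  dy <- wrap_diff(y1 - y2, space$height)
  d <- sqrt(dx^2 + dy^2)
  if (distance_mode == "euclidean_truncated") d <- floor(d)
  d
}

#' Maximum attainable pairwise distance on a torus
#'
#' `sqrt((width/2)^2 + (height/2)^2)` using integer half-axes (`floor(L/2)`),
#' the farthest any two grid cells can be. For the canonical 315 x 315 grid
#' this is `sqrt(2 * 157^2)`, about 222.
#'
#' @param space A [torus_space()].
#' @return A single nonnegative number.
#' @export
max_torus_distance <- function(space) {
  sqrt((space$width %/% 2)^2 + (space$height %/% 2)^2)
}
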