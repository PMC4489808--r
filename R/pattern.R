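#' Planar point pattern of home-base locations
#'
#' Container for the locations of the individuals in a population (their
#' nests or home bases), each carrying an interaction radius that defines
#' its circular zone of influence, observed inside an axis-aligned
#' rectangular window.
#'
#' @param x,y numeric coordinates of the n individuals.
#' @param ids character or integer identifiers; defaults to `1:n`.
#'   Must be unique.
#' @param radii positive interaction radius per individual; a single value
#'   is recycled. May be `NA` if radii will be supplied later (e.g. chosen
#'   from the pair correlation function).
#' @param window observation window `c(x0, x1, y0, y1)`. Defaults to the
#'   unit square. All points must lie inside it.
#'
#' @return An object of class `"snbda_pattern"`: a list with elements
#'   `ids`, `x`, `y`, `radii`, `window`, `n`.
#' @export
point_pattern <- function(x, y, ids = NULL, radii = NA_real_,
                          window = c(0, 1, 0, 1)) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 1L) stop("a point pattern needs at least one point")
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in point pattern")
  if (length(ids) != n) stop("ids must match the number of points")
  window <- as.numeric(window)
  if (length(window) != 4L || window[1] >= window[2] || window[3] >= window[4])
    stop("window must be c(x0, x1, y0, y1) with x0 < x1 and y0 < y1")
  if (any(x < window[1] | x > window[2] | y < window[3] | y > window[4]))
    stop("all points must lie inside the window")
  radii <- rep_len(as.numeric(radii), n)
  if (any(!is.na(radii) & radii <= 0)) stop("interaction radii must be positive")
  structure(
    list(ids = ids, x = x, y = y, radii = radii, window = window, n = n),
    class = "snbda_pattern"
  )
}

#' @export
print.snbda_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in [%g, %g] x [%g, %g]\n",
              x$n, x$window[1], x$window[2], x$window[3], x$window[4]))
  r <- unique(x$radii)
  if (all(is.na(r))) cat("  interaction radii: unset\n")
  else if (length(r) == 1L) cat(sprintf("  interaction radius: %g\n", r))
  else cat(sprintf("  interaction radii: %d distinct values\n", length(r)))
  invisible(x)
}

window_area <- function(pattern) {
  w <- pattern$window
  (w[2] - w[1]) * (w[4] - w[3])
}

#' Intensity of a point pattern
#'
#' Number of points per unit area, `n / |W|`.
#'
#' @param pattern a [point_pattern()].
#' @return numeric intensity estimate.
#' @export
intensity <- function(pattern) {
  stopifnot(inherits(pattern, "snbda_pattern"))
  pattern$n / window_area(pattern)
}

pairwise_distances <- function(pattern) {
  as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
}
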