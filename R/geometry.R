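#' Zone-of-influence disc
#'
#' A circular zone of influence: the region within which an individual
#' forages, exerts influence, or — in the diffusion setting — transmits
#' information. Constant influence throughout the disc is assumed.
#'
#' @param center numeric length-2 vector, the disc center.
#' @param radius positive interaction radius.
#' @return An object of class `"snbda_disc"`.
#' @export
disc <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 2L || any(!is.finite(center)))
    stop("center must be two finite coordinates")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number")
  structure(list(center = center, radius = radius), class = "snbda_disc")
}

# closed-form circle-circle lens area; d = center distance
lens_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  # two circular segments; clamp acos arguments against roundoff
  a1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  a2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
  a1 <- min(1, max(-1, a1))
  a2 <- min(1, max(-1, a2))
  r1^2 * acos(a1) + r2^2 * acos(a2) -
    0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) *
                      (d - r1 + r2) * (d + r1 + r2)))
}

#' Exact area of intersection of two zones of influence
#'
#' Closed-form circle–circle lens area: 0 for disjoint discs, the full
#' area of the smaller disc when one contains the other, otherwise the
#' sum of the two circular segments cut off by the chord through the
#' intersection points.
#'
#' @param d1,d2 discs created with [disc()].
#' @return non-negative overlap area.
#' @seealso [disc_overlap_area_mc()] for the Monte Carlo estimate.
#' @export
disc_overlap_area <- function(d1, d2) {
  stopifnot(inherits(d1, "snbda_disc"), inherits(d2, "snbda_disc"))
  d <- sqrt(sum((d1$center - d2$center)^2))
  lens_area(d, d1$radius, d2$radius)
}

#' Monte Carlo estimate of the disc overlap area
#'
#' Hit-or-miss estimate: points are sampled uniformly in the bounding box
#' of the intersection region (the intersection of the two discs' bounding
#' boxes) and the fraction landing inside both discs is scaled by the box
#' area. Unbiased; retained as a cross-check of [disc_overlap_area()] and
#' for parity with simulation-based association pipelines.
#'
#' @inheritParams disc_overlap_area
#' @param n_samples number of uniform samples (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return non-negative area estimate; exactly 0 for disjoint discs.
#' @export
disc_overlap_area_mc <- function(d1, d2, n_samples = 1e5, seed = NULL) {
  stopifnot(inherits(d1, "snbda_disc"), inherits(d2, "snbda_disc"))
  if (n_samples < 1) stop("n_samples must be at least 1")
  lo <- pmax(d1$center - d1$radius, d2$center - d2$radius)
  hi <- pmin(d1$center + d1$radius, d2$center + d2$radius)
  if (any(hi <= lo)) return(0)
  if (!is.null(seed)) set.seed(seed)
  px <- stats::runif(n_samples, lo[1], hi[1])
  py <- stats::runif(n_samples, lo[2], hi[2])
  inside <- ((px - d1$center[1])^2 + (py - d1$center[2])^2 <= d1$radius^2) &
            ((px - d2$center[1])^2 + (py - d2$center[2])^2 <= d2$radius^2)
  mean(inside) * prod(hi - lo)
}

#' Spatially derived association matrix
#'
#' Builds the n x n matrix of inter-individual associations from the
#' overlap of zones of influence. The entry in row i, column j quantifies
#' the influence of individual j on individual i:
#' `|Z_i intersect Z_j| / |Z_i|` under the default receiver normalisation
#' — the proportion of i's own zone shared with j, i.e. the proportion of
#' time i spends under j's influence. With `normalise = "sender"` the
#' denominator is the sender j's zone area instead. Entries lie in
#' \[0, 1\]; the diagonal is zero; the matrix is symmetric whenever all
#' interaction radii are equal and asymmetric otherwise (a smaller-radius
#' individual devotes a larger share of its zone to the overlap).
#'
#' @param pattern a [point_pattern()] with positive radii, or radii
#'   supplied through `radius`.
#' @param radius optional single interaction radius overriding the
#'   pattern's radii (applied to every individual).
#' @param normalise `"receiver"` (default) or `"sender"`.
#' @return matrix of class `"snbda_assoc"` with ids as dimnames.
#' @export
association_matrix <- function(pattern, radius = NULL,
                               normalise = c("receiver", "sender")) {
  stopifnot(inherits(pattern, "snbda_pattern"))
  normalise <- match.arg(normalise)
  n <- pattern$n
  if (n < 2L) stop("association matrix needs at least two individuals")
  radii <- if (!is.null(radius)) rep_len(as.numeric(radius), n) else pattern$radii
  if (any(is.na(radii)) || any(radii <= 0))
    stop("all interaction radii must be positive; set them on the pattern or pass `radius`")
  A <- matrix(0, n, n, dimnames = list(pattern$ids, pattern$ids))
  zone <- pi * radii^2
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt((pattern$x[i] - pattern$x[j])^2 + (pattern$y[i] - pattern$y[j])^2)
      ov <- lens_area(d, radii[i], radii[j])
      if (ov > 0) {
        if (normalise == "receiver") {
          A[i, j] <- ov / zone[i]   # influence of j on receiver i
          A[j, i] <- ov / zone[j]
        } else {
          A[i, j] <- ov / zone[j]   # normalised by sender j
          A[j, i] <- ov / zone[i]
        }
      }
    }
  }
  class(A) <- c("snbda_assoc", "matrix", "array")
  A
}

#' @export
print.snbda_assoc <- function(x, ...) {
  cat(sprintf("Association matrix (%d x %d), %d non-zero entries\n",
              nrow(x), ncol(x), sum(x > 0)))
  invisible(x)
}
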