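#' Ripley's K function with translation edge correction
#'
#' Estimates `K(r) = intensity^-1 * E[number of further points within
#' distance r of a typical point]`. Each ordered pair (i, j) with
#' `d_ij <= r` contributes with the translation edge-correction weight
#' `|W| / ((a - |dx|)(b - |dy|))`, unbiased on rectangular windows.
#' Under complete spatial randomness `K(r) = pi r^2`.
#'
#' @param pattern a [point_pattern()] with n >= 2.
#' @param r_grid increasing vector of distances; values at or beyond half
#'   the shorter window side are unreliable and returned as `NA` with a
#'   warning.
#' @return numeric vector of K estimates along `r_grid`.
#' @export
ripley_k <- function(pattern, r_grid) {
  stopifnot(inherits(pattern, "snbda_pattern"))
  if (pattern$n < 2L) stop("Ripley's K needs at least two points")
  r_grid <- as.numeric(r_grid)
  if (is.unsorted(r_grid, strictly = TRUE)) stop("r_grid must be strictly increasing")
  w <- pattern$window
  sides <- c(w[2] - w[1], w[4] - w[3])
  ok <- r_grid < min(sides) / 2
  if (!all(ok))
    warning("r values at or beyond half the shorter window side are flagged NA")
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  d <- sqrt(dx^2 + dy^2)
  keep <- upper.tri(d)
  dx <- dx[keep]; dy <- dy[keep]; d <- d[keep]
  area <- prod(sides)
  # translation correction: weight per ordered pair; each unordered pair
  # counted twice with the same weight
  wt <- 2 * area / ((sides[1] - dx) * (sides[2] - dy))
  n <- pattern$n
  # K = |W|^2/(n(n-1)) * sum over ordered pairs of 1/A_ij; wt carries one
  # factor of |W| already
  k <- area * vapply(r_grid, function(r) sum(wt[d <= r]), numeric(1)) /
    (n * (n - 1))
  k[!ok] <- NA_real_
  k
}

#' Pair correlation function
#'
#' Kernel-smoothed estimate of the pair correlation function g(r), the
#' derivative form of Ripley's K: `g(r) = K'(r) / (2 pi r)`. Values above
#' 1 indicate clustering at scale r, below 1 regularity, and 1 complete
#' spatial randomness (CSR). Pairwise distances are smoothed with an
#' Epanechnikov kernel and weighted by the translation edge correction.
#'
#' The estimate is flagged unreliable (`reliable = FALSE`, `g = NA`)
#' where fewer than 5 pairwise distances fall within one bandwidth of
#' r, and at r smaller than one bandwidth, where the kernel window
#' extends below zero distance and the `1/(2 pi r)` factor inflates the
#' estimate. At such scales the pair correlation plot is undefined or
#' unreliable and they should not be used as interaction radii.
#'
#' @inheritParams ripley_k
#' @param r_grid distances at which to estimate g; default 50 points up
#'   to a quarter of the shorter window side.
#' @param bandwidth Epanechnikov half-width, or `"auto"` for Stoyan's
#'   rule of thumb `0.15 / sqrt(intensity)`.
#' @param n_sim if > 0, a CSR simulation envelope with this many
#'   replicates is attached (see [csr_envelope()]).
#' @param seed seed for the envelope simulations.
#' @return A data frame of class `"snbda_pcf"` with columns `r`, `g`,
#'   `k`, `reliable` and, when an envelope is requested, `env_low`,
#'   `env_high`. The bandwidth used is stored as attribute `"bandwidth"`.
#' @export
pair_correlation <- function(pattern, r_grid = NULL, bandwidth = "auto",
                             n_sim = 0, seed = NULL) {
  stopifnot(inherits(pattern, "snbda_pattern"))
  if (pattern$n < 2L) stop("pair correlation needs at least two points")
  w <- pattern$window
  sides <- c(w[2] - w[1], w[4] - w[3])
  if (is.null(r_grid)) {
    rmax <- min(sides) / 4
    r_grid <- seq(rmax / 50, rmax, length.out = 50)
  }
  r_grid <- as.numeric(r_grid)
  if (is.unsorted(r_grid, strictly = TRUE)) stop("r_grid must be strictly increasing")
  if (identical(bandwidth, "auto")) bandwidth <- 0.15 / sqrt(intensity(pattern))
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive")

  est <- pcf_estimate(pattern, r_grid, bandwidth)
  k <- suppressWarnings(ripley_k(pattern, r_grid))
  out <- data.frame(r = r_grid, g = est$g, k = k, reliable = est$reliable)
  if (n_sim > 0) {
    env <- csr_envelope(pattern, r_grid, n_sim = n_sim, seed = seed,
                        bandwidth = bandwidth)
    out$env_low <- env$low
    out$env_high <- env$high
    attr(out, "n_sim") <- n_sim
  }
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("snbda_pcf", "data.frame")
  out
}

# core kernel estimator, shared by pair_correlation and csr_envelope
pcf_estimate <- function(pattern, r_grid, bandwidth) {
  w <- pattern$window
  sides <- c(w[2] - w[1], w[4] - w[3])
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  d <- sqrt(dx^2 + dy^2)
  keep <- upper.tri(d)
  dx <- dx[keep]; dy <- dy[keep]; d <- d[keep]
  area <- prod(sides)
  wt <- 2 * area / ((sides[1] - dx) * (sides[2] - dy))
  n <- pattern$n
  h <- bandwidth
  g <- numeric(length(r_grid))
  reliable <- logical(length(r_grid))
  for (m in seq_along(r_grid)) {
    r <- r_grid[m]
    u <- (d - r) / h
    inwin <- abs(u) < 1
    # r below one bandwidth sits in the kernel's boundary region at 0,
    # where the estimate is biased upward (no distances exist below 0
    # and the 1/2*pi*r factor blows up); flagged with the sparse cases
    reliable[m] <- sum(inwin) >= 5L && r >= h
    kern <- 0.75 * (1 - u[inwin]^2) / h           # Epanechnikov
    g[m] <- area * sum(wt[inwin] * kern) / (n * (n - 1) * 2 * pi * r)
  }
  g[!reliable] <- NA_real_
  list(g = g, reliable = reliable)
}

#' CSR simulation envelope for the pair correlation function
#'
#' Pointwise min/max envelope of g(r) across `n_sim` binomial-process
#' patterns (the same number of points placed uniformly in the same
#' window). An empirical curve above the envelope is evidence of
#' clustering at that distance, below it of regularity; a curve inside
#' the envelope is consistent with CSR.
#'
#' @inheritParams pair_correlation
#' @param n_sim number of CSR replicates (>= 2); 99 is a common choice.
#' @param seed integer seed; the envelope is reproducible given it.
#' @return data frame with columns `r`, `low`, `high`.
#' @export
csr_envelope <- function(pattern, r_grid, n_sim = 99, seed = NULL,
                         bandwidth = "auto") {
  stopifnot(inherits(pattern, "snbda_pattern"))
  if (n_sim < 2) stop("n_sim must be at least 2")
  if (identical(bandwidth, "auto")) bandwidth <- 0.15 / sqrt(intensity(pattern))
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(NA_real_, n_sim, length(r_grid))
  for (s in seq_len(n_sim)) {
    p <- simulate_csr(pattern$n, window = pattern$window)
    sims[s, ] <- pcf_estimate(p, r_grid, bandwidth)$g
  }
  data.frame(
    r = r_grid,
    low = apply(sims, 2, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)),
    high = apply(sims, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  )
}

#' Suggest an interaction radius from the pair correlation function
#'
#' Selects the distance at which the empirical pair correlation departs
#' most strongly from the CSR envelope: for a clustered pattern, the r
#' where g most exceeds the upper envelope; if g never exceeds it but
#' falls below the lower envelope, the r of the strongest deficit is
#' returned with a `"regular"` flag. Ties are broken toward smaller r,
#' since associations act at local scales and large spatial scales
#' should be avoided. Only distances where the estimate is reliable are
#' considered.
#'
#' @param pcf a [pair_correlation()] result carrying an envelope.
#' @return list with elements `radius` (NA when the pattern is
#'   consistent with CSR), `type` (`"clustered"`, `"regular"` or
#'   `"csr"`), and `excess` (the signed departure at the chosen r).
#' @export
suggest_interaction_radius <- function(pcf) {
  stopifnot(inherits(pcf, "snbda_pcf"))
  if (is.null(pcf$env_low) || is.null(pcf$env_high))
    stop("pcf must carry a CSR envelope; rerun pair_correlation() with n_sim > 0")
  ok <- pcf$reliable & !is.na(pcf$g) & !is.na(pcf$env_high)
  if (!any(ok)) return(list(radius = NA_real_, type = "csr", excess = NA_real_))
  r <- pcf$r[ok]; g <- pcf$g[ok]
  hi <- pcf$env_high[ok]; lo <- pcf$env_low[ok]
  over <- g - hi
  if (any(over > 0)) {
    best <- which(over == max(over))[1]   # first index = smallest r on ties
    return(list(radius = r[best], type = "clustered", excess = over[best]))
  }
  under <- g - lo
  if (any(under < 0)) {
    best <- which(under == min(under))[1]
    return(list(radius = r[best], type = "regular", excess = under[best]))
  }
  list(radius = NA_real_, type = "csr", excess = NA_real_)
}

#' Area of the union of zones of influence
#'
#' Grid-based estimate of the area of the union of discs of radius r
#' centred at the points of the pattern, clipped to the observation
#' window — the geometric term of the area-interaction point-process
#' density. The window is discretised into `resolution^2` cells and the
#' fraction of cell centres covered by at least one disc is scaled by
#' the window area.
#'
#' @inheritParams ripley_k
#' @param r disc radius (> 0).
#' @param resolution cells per side of the grid (default 512).
#' @return non-negative area, at most the window area.
#' @export
union_of_discs_area <- function(pattern, r, resolution = 512) {
  stopifnot(inherits(pattern, "snbda_pattern"))
  if (!is.numeric(r) || r <= 0) stop("r must be positive")
  w <- pattern$window
  gx <- seq(w[1], w[2], length.out = resolution + 1L)
  gx <- (gx[-1] + gx[-length(gx)]) / 2
  gy <- seq(w[3], w[4], length.out = resolution + 1L)
  gy <- (gy[-1] + gy[-length(gy)]) / 2
  covered <- matrix(FALSE, resolution, resolution)
  r2 <- r^2
  for (i in seq_len(pattern$n)) {
    xi <- pattern$x[i]; yi <- pattern$y[i]
    jx <- which(abs(gx - xi) <= r)
    if (!length(jx)) next
    jy <- which(abs(gy - yi) <= r)
    if (!length(jy)) next
    sub <- outer((gx[jx] - xi)^2, (gy[jy] - yi)^2, "+") <= r2
    covered[jx, jy] <- covered[jx, jy] | sub
  }
  mean(covered) * window_area(pattern)
}

#' Unnormalised log-density of the area-interaction point process
#'
#' Evaluates `n log(xi) - |U| log(gamma) + c log(beta)` where `|U|` is
#' the union-of-discs area of the pattern at radius r: the log of the
#' unnormalised area-interaction density `xi^n * gamma^{-|U|} * beta^c`.
#' `gamma > 1` rewards overlapping zones (attraction between
#' individuals), `gamma < 1` penalises them (repulsion), and `gamma = 1`
#' reduces to a Poisson process. No fitting is performed.
#'
#' @inheritParams union_of_discs_area
#' @param xi intensity parameter (> 0).
#' @param gamma interaction parameter (> 0).
#' @param beta covariate-effect parameter (> 0).
#' @param covariate_total the pattern's total covariate value c.
#' @return the unnormalised log-density.
#' @export
area_interaction_logdensity <- function(pattern, r, xi, gamma, beta,
                                        covariate_total = 0,
                                        resolution = 512) {
  if (!is.numeric(xi) || xi <= 0 || !is.numeric(gamma) || gamma <= 0 ||
      !is.numeric(beta) || beta <= 0)
    stop("xi, gamma and beta must all be positive")
  n <- if (is.null(pattern)) 0L else pattern$n
  u <- if (n == 0L) 0 else union_of_discs_area(pattern, r, resolution)
  n * log(xi) - u * log(gamma) + covariate_total * log(beta)
}
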