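test_that("Ripley's K is close to pi r^2 under CSR", {
  p <- simulate_csr(500, seed = 101)
  r <- seq(0.02, 0.2, by = 0.02)
  k <- ripley_k(p, r)
  expect_true(mean(k / (pi * r^2)) > 0.9 && mean(k / (pi * r^2)) < 1.1)
})

test_that("Ripley's K edge cases behave", {
  # two points at distance 0.5: no pairs within r = 0.4
  p <- point_pattern(c(0.25, 0.75), c(0.5, 0.5))
  expect_equal(ripley_k(p, 0.4), 0)
  # coincident points: every pair within any r > 0, K near the window area
  pd <- point_pattern(rep(0.5, 20), rep(0.5, 20))
  expect_gt(ripley_k(pd, 0.01), 50 * pi * 0.01^2)
  # r beyond half the shorter side is flagged
  expect_warning(kk <- ripley_k(p, c(0.1, 0.6)), "half the shorter")
  expect_true(is.na(kk[2]) && !is.na(kk[1]))
  expect_error(ripley_k(point_pattern(0.5, 0.5), 0.1), "two points")
})

test_that("pair correlation separates clustered, random and inhibited patterns", {
  # hard-core pattern: g < 1 below the hard-core distance where defined
  ph <- make_hardcore_pattern(120, 0.08, seed = 3)
  r <- seq(0.01, 0.12, by = 0.005)
  g <- pair_correlation(ph, r)$g
  below <- r < 0.08 & !is.na(g)
  expect_true(all(g[below] < 1))

  # Matern cluster pattern: g rises above 1 within the cluster radius
  pm <- simulate_matern_cluster(8, 25, 0.05, seed = 4)
  gm <- pair_correlation(pm, seq(0.01, 0.1, by = 0.005))
  expect_gt(max(gm$g, na.rm = TRUE), 1)

  # invariant under point relabelling
  set.seed(9)
  p <- simulate_csr(80, seed = 10)
  perm <- sample(p$n)
  pp <- point_pattern(p$x[perm], p$y[perm], window = p$window)
  r2 <- seq(0.02, 0.2, by = 0.02)
  expect_equal(pair_correlation(pp, r2)$g, pair_correlation(p, r2)$g)
  expect_equal(ripley_k(pp, r2), ripley_k(p, r2))
})

test_that("pair correlation flags unreliable distances and bad bandwidths", {
  p <- simulate_csr(20, seed = 5)
  pc <- pair_correlation(p, c(0.001, 0.1), bandwidth = 0.005)
  expect_false(pc$reliable[1])   # essentially no pairs that close
  expect_true(is.na(pc$g[1]))
  expect_error(pair_correlation(p, bandwidth = -1), "bandwidth")
})

test_that("CSR envelopes are reproducible, ordered, and calibrated", {
  p <- simulate_csr(60, seed = 21)
  r <- seq(0.02, 0.2, by = 0.01)
  e1 <- csr_envelope(p, r, n_sim = 19, seed = 33)
  e2 <- csr_envelope(p, r, n_sim = 19, seed = 33)
  expect_identical(e1, e2)
  expect_true(all(e1$low <= e1$high, na.rm = TRUE))
  # a CSR pattern should sit mostly inside its own envelope
  pc <- pair_correlation(p, r, n_sim = 39, seed = 44)
  ok <- pc$reliable
  inside <- pc$g[ok] >= pc$env_low[ok] & pc$g[ok] <= pc$env_high[ok]
  expect_gt(mean(inside), 0.8)
})

test_that("interaction-radius suggestion picks the strongest departure", {
  fake <- function(g, hi, lo, r = seq(0.01, 0.1, by = 0.01)) {
    out <- data.frame(r = r, g = g, k = NA, reliable = TRUE,
                      env_low = lo, env_high = hi)
    class(out) <- c("snbda_pcf", "data.frame")
    out
  }
  r <- seq(0.01, 0.1, by = 0.01)
  # single spike above the envelope at r = 0.05
  g <- rep(1, 10); g[r == 0.05] <- 3
  s <- suggest_interaction_radius(fake(g, hi = rep(1.5, 10), lo = rep(0.5, 10)))
  expect_equal(s$radius, 0.05)
  expect_equal(s$type, "clustered")
  # everywhere inside: CSR flag, no radius
  s2 <- suggest_interaction_radius(fake(rep(1, 10), rep(1.5, 10), rep(0.5, 10)))
  expect_true(is.na(s2$radius))
  expect_equal(s2$type, "csr")
  # below the lower envelope only: regularity flag
  g3 <- rep(1, 10); g3[3] <- 0.1
  s3 <- suggest_interaction_radius(fake(g3, rep(1.5, 10), rep(0.5, 10)))
  expect_equal(s3$type, "regular")
  expect_equal(s3$radius, r[3])
  # ties broken toward smaller r
  g4 <- rep(1, 10); g4[c(4, 8)] <- 3
  s4 <- suggest_interaction_radius(fake(g4, rep(1.5, 10), rep(0.5, 10)))
  expect_equal(s4$radius, r[4])
  expect_error(suggest_interaction_radius(pair_correlation(simulate_csr(20, seed = 1))),
               "envelope")
})

test_that("union-of-discs area matches inclusion-exclusion", {
  # one interior disc
  p1 <- point_pattern(0.5, 0.5)
  expect_equal(union_of_discs_area(p1, 0.1, resolution = 768), pi * 0.01,
               tolerance = 0.01)
  # two disjoint interior discs: areas add
  p2 <- point_pattern(c(0.25, 0.75), c(0.5, 0.5))
  expect_equal(union_of_discs_area(p2, 0.1, resolution = 768), 2 * pi * 0.01,
               tolerance = 0.01)
  # two overlapping discs: inclusion-exclusion with the lens oracle
  p3 <- point_pattern(c(0.45, 0.55), c(0.5, 0.5))
  lens <- disc_overlap_area(disc(c(0.45, 0.5), 0.1), disc(c(0.55, 0.5), 0.1))
  expect_equal(union_of_discs_area(p3, 0.1, resolution = 768),
               2 * pi * 0.01 - lens, tolerance = 0.01)
  # monotone non-decreasing in r, bounded by the window area
  p <- simulate_csr(15, seed = 8)
  u <- vapply(c(0.02, 0.05, 0.1, 0.3), function(r)
    union_of_discs_area(p, r, resolution = 256), numeric(1))
  expect_true(all(diff(u) >= 0))
  expect_true(all(u <= 1 + 1e-12))
  expect_error(union_of_discs_area(p, -0.1), "positive")
})

test_that("area-interaction log-density has the right structure", {
  p <- simulate_csr(12, seed = 13)
  # gamma = 1, beta = 1: only the intensity term survives
  expect_equal(area_interaction_logdensity(p, r = 0.05, xi = 2, gamma = 1,
                                           beta = 1, resolution = 128),
               12 * log(2))
  # doubling xi adds n log 2
  l1 <- area_interaction_logdensity(p, 0.05, xi = 1.5, gamma = 2, beta = 1.2,
                                    covariate_total = 0.7, resolution = 128)
  l2 <- area_interaction_logdensity(p, 0.05, xi = 3, gamma = 2, beta = 1.2,
                                    covariate_total = 0.7, resolution = 128)
  expect_equal(l2 - l1, 12 * log(2), tolerance = 1e-10)
  # empty pattern: only the covariate term
  expect_equal(area_interaction_logdensity(NULL, 0.05, xi = 2, gamma = 3,
                                           beta = 2, covariate_total = 1.5),
               1.5 * log(2))
  expect_error(area_interaction_logdensity(p, 0.05, xi = -1, gamma = 1, beta = 1),
               "positive")
})
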