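# Shared helpers: independent oracles and small generators used across
# the unit tests. These deliberately take different code paths from the
# implementation they check.

# simple sequential-inhibition (hard-core) pattern: proposals that fall
# within `hardcore` of an accepted point are discarded
make_hardcore_pattern <- function(n, hardcore, window = c(0, 1, 0, 1),
                                  seed = 1) {
  set.seed(seed)
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < 50000L) {
    tries <- tries + 1L
    x <- runif(1, window[1], window[2])
    y <- runif(1, window[3], window[4])
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= hardcore^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  point_pattern(xs, ys, window = window)
}

# closed-form simple OLS via the normal equations (oracle for the wave fit)
ols_closed_form <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, se = se, r2 = r2)
}

# log-likelihood oracle built from the exported hazard() operation:
# walks the event history interval by interval, so it shares no code
# with the precomputed-context likelihood
loglik_hazard_oracle <- function(record, A, covariates, params) {
  n <- length(record$ids)
  if (is.null(covariates)) covariates <- numeric(n)
  times <- record$times
  cens <- record$censored
  ev <- order(times)[!cens[order(times)]]
  ev <- ev[order(times[ev])]
  informed <- rep(FALSE, n)
  t_prev <- 0
  ll <- 0
  for (k in ev) {
    tk <- times[k]
    for (i in which(!informed))
      ll <- ll - hazard(i, informed, params, A, covariates) * (tk - t_prev)
    ll <- ll + log(hazard(k, informed, params, A, covariates))
    informed[k] <- TRUE
    t_prev <- tk
  }
  if (any(cens) && is.finite(record$horizon)) {
    for (i in which(!informed))
      ll <- ll - hazard(i, informed, params, A, covariates) *
        (record$horizon - t_prev)
  }
  ll
}

unit_disc_pair <- function(d, r1 = 1, r2 = 1) {
  list(disc(c(0, 0), r1), disc(c(d, 0), r2))
}
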