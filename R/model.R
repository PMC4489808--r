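#' Parameter set for the nested social-transmission models
#'
#' The three nested hazard models are: model 1 (null) with the baseline
#' asocial rate `lambda0` only; model 2 adding the social transmission
#' rate `s_prime` (per unit association with informed individuals); and
#' model 3 (full) adding the environmental effect `beta`, which scales
#' the asocial rate multiplicatively as `exp(beta * c_i)`.
#'
#' `lambda0` and `s_prime` are held on the natural-log scale with
#' Uniform(-10, 10) priors (closed interval: the boundary is inside the
#' support). The environmental effect is a signed real: by default the
#' Uniform(-10, 10) prior applies to the log of its magnitude with an
#' even prior on the sign (`beta_prior = "signed-log"`); alternatively
#' a flat Uniform(-10, 10) prior on beta itself (`beta_prior =
#' "uniform"`).
#'
#' @param model_id 1, 2 or 3.
#' @param log_lambda0 log baseline rate.
#' @param log_s_prime log social rate (models 2 and 3).
#' @param beta signed environmental effect (model 3).
#' @param prior_low,prior_high box-prior bounds (defaults -10, 10).
#' @param tuning named proposal half-widths epsilon per parameter;
#'   defaults `log_lambda0 = 1`, `log_s_prime = 1`, `beta = 3`.
#' @param beta_prior `"signed-log"` (default) or `"uniform"`.
#' @return object of class `"snbda_params"`.
#' @export
parameter_set <- function(model_id, log_lambda0, log_s_prime = NULL,
                          beta = NULL, prior_low = -10, prior_high = 10,
                          tuning = NULL,
                          beta_prior = c("signed-log", "uniform")) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3")
  beta_prior <- match.arg(beta_prior)
  if (model_id >= 2 && is.null(log_s_prime))
    stop("models 2 and 3 require log_s_prime")
  if (model_id == 3 && is.null(beta)) stop("model 3 requires beta")
  if (model_id == 1) log_s_prime <- NULL
  if (model_id < 3) beta <- NULL
  tun <- c(log_lambda0 = 1, log_s_prime = 1, beta = 3)
  if (!is.null(tuning)) {
    if (any(tuning <= 0)) stop("tuning widths must be positive")
    tun[names(tuning)] <- tuning
  }
  structure(list(model_id = model_id, log_lambda0 = log_lambda0,
                 log_s_prime = log_s_prime, beta = beta,
                 prior_low = prior_low, prior_high = prior_high,
                 tuning = tun, beta_prior = beta_prior),
            class = "snbda_params")
}

param_names <- function(model_id) {
  switch(model_id, c("log_lambda0"),
         c("log_lambda0", "log_s_prime"),
         c("log_lambda0", "log_s_prime", "beta"))
}

#' Log-prior of a parameter set
#'
#' Box priors: Uniform(-10, 10) on each log-scale parameter, evaluated
#' as 0 inside the (closed) box and `-Inf` outside, up to a constant.
#' Under the default signed-log parameterisation of the environmental
#' effect the prior applies to `log(abs(beta))` with an even prior on
#' the sign; under `beta_prior = "uniform"` it applies to beta itself.
#'
#' @param params a [parameter_set()].
#' @return 0 inside the prior support, `-Inf` outside.
#' @export
log_prior <- function(params) {
  stopifnot(inherits(params, "snbda_params"))
  lo <- params$prior_low; hi <- params$prior_high
  vals <- c(params$log_lambda0, params$log_s_prime)
  if (!is.null(params$beta)) {
    b <- if (params$beta_prior == "signed-log") log(abs(params$beta))
         else params$beta
    vals <- c(vals, b)
  }
  if (any(vals < lo | vals > hi)) -Inf else 0
}

#' Hazard rate of a naive individual
#'
#' The instantaneous rate at which individual i first performs the
#' behaviour: zero once informed, otherwise the social term (rate
#' `s_prime` per unit association with currently informed individuals)
#' plus the asocial baseline `lambda0 * exp(beta * c_i)`.
#'
#' @param i individual index (1-based).
#' @param informed logical or 0/1 status vector z.
#' @param params a [parameter_set()].
#' @param A association matrix.
#' @param covariates per-individual covariate values (required for
#'   model 3).
#' @return non-negative rate.
#' @export
hazard <- function(i, informed, params, A, covariates = NULL) {
  stopifnot(inherits(params, "snbda_params"))
  A <- as.matrix(A)
  n <- nrow(A)
  if (i < 1 || i > n) stop("individual index out of range")
  informed <- as.logical(informed)
  if (length(informed) != n) stop("informed status must match the matrix")
  if (informed[i]) return(0)
  lambda0 <- exp(params$log_lambda0)
  social <- if (params$model_id >= 2)
    exp(params$log_s_prime) * sum(A[i, informed]) else 0
  asocial <- if (params$model_id == 3) {
    if (is.null(covariates) || is.na(covariates[i]))
      stop("model 3 requires finite covariates")
    lambda0 * exp(params$beta * covariates[i])
  } else lambda0
  social + asocial
}

# --- likelihood internals -------------------------------------------------
#
# The hazards are piecewise constant between acquisition events (the
# network and covariates are static), so the log-likelihood is
#   sum_events log lambda_learner(t_k-)  -  sum_i integral_0^min(t_i,T) lambda_i
# and both pieces reduce to sums that are precomputable once per dataset:
#   ev_S: social association sum of each learner at its event
#   ev_c: covariate of each learner
#   social_exposure: sum over intervals of dt * sum_{naive i} S_i (scalar)
#   exposure_i: total naive time of individual i
# giving
#   ll = sum log(s' ev_S + l0 e^{b ev_c}) - s' * social_exposure
#        - l0 * sum_i e^{b c_i} exposure_i.

diffusion_context <- function(record, A, covariates = NULL,
                              innovator_seeded = FALSE,
                              ties = c("error", "jitter")) {
  stopifnot(inherits(record, "snbda_diffusion"))
  ties <- match.arg(ties)
  A <- as.matrix(A)
  n <- length(record$ids)
  if (nrow(A) != n || ncol(A) != n)
    stop("association matrix does not match the diffusion record")
  if (is.null(covariates)) covariates <- numeric(n)
  if (length(covariates) != n) stop("covariates must match the record")
  if (anyNA(covariates)) stop("covariates must be finite")
  times <- record$times
  cens <- record$censored
  horizon <- record$horizon
  if (!any(!cens)) stop("diffusion record has no uncensored acquisition")
  ev_t <- times[!cens]
  if (anyDuplicated(ev_t)) {
    if (ties == "error")
      stop("tied event times; resolve them or use ties = \"jitter\"")
    warning("tied event times jittered by 1e-9 * max(time)")
    jit <- 1e-9 * max(ev_t)
    while (anyDuplicated(times[!cens])) {
      dup <- which(!cens & duplicated(times))
      times[dup] <- times[dup] + jit
    }
  }
  ord <- order(replace(times, cens, Inf))
  end_t <- if (is.finite(horizon)) horizon else max(times[!cens])
  # walk through events in time order, accumulating exposures
  z <- logical(n)
  if (innovator_seeded) {
    innov <- which(record$ids == record$innovator)
    z[innov] <- TRUE
  }
  t_prev <- 0
  exposure <- numeric(n)
  social_exposure <- 0
  ev_S <- numeric(0); ev_c <- numeric(0)
  for (k in ord) {
    if (cens[k]) break
    tk <- times[k]
    dt <- tk - t_prev
    naive <- !z
    exposure[naive] <- exposure[naive] + dt
    if (any(z)) {
      S <- as.numeric(A[naive, z, drop = FALSE] %*% rep(1, sum(z)))
      social_exposure <- social_exposure + dt * sum(S)
    }
    if (!(innovator_seeded && z[k])) {
      if (z[k]) stop("event recorded for an already informed individual")
      ev_S <- c(ev_S, sum(A[k, z]))
      ev_c <- c(ev_c, covariates[k])
    }
    z[k] <- TRUE
    t_prev <- tk
  }
  if (any(cens)) {
    dt <- end_t - t_prev
    if (dt > 0) {
      naive <- !z
      exposure[naive] <- exposure[naive] + dt
      if (any(z)) {
        S <- as.numeric(A[naive, z, drop = FALSE] %*% rep(1, sum(z)))
        social_exposure <- social_exposure + dt * sum(S)
      }
    }
  }
  list(ev_S = ev_S, ev_c = ev_c, social_exposure = social_exposure,
       exposure = exposure, covariates = covariates)
}

ll_context <- function(ctx, model_id, lambda0, s_prime = 0, beta = 0) {
  if (model_id < 3) beta <- 0
  if (model_id < 2) s_prime <- 0
  rates <- s_prime * ctx$ev_S + lambda0 * exp(beta * ctx$ev_c)
  if (any(rates <= 0)) return(-Inf)
  v <- sum(log(rates)) - s_prime * ctx$social_exposure -
    lambda0 * sum(exp(beta * ctx$covariates) * ctx$exposure)
  # overflowing exp() terms produce Inf - Inf: treat as impossible
  if (!is.finite(v)) -Inf else v
}

ll_contexts <- function(ctxs, model_id, lambda0, s_prime = 0, beta = 0) {
  tot <- 0
  for (ctx in ctxs) {
    v <- ll_context(ctx, model_id, lambda0, s_prime, beta)
    if (!is.finite(v)) return(v)
    tot <- tot + v
  }
  tot
}

#' Continuous-time diffusion log-likelihood (TADA)
#'
#' Event-history log-likelihood of the exact acquisition times under the
#' social-transmission hazard model: the sum over acquisition events of
#' the log-hazard of the learner just before its event, minus every
#' individual's integrated hazard over the time it remained naive
#' (censored individuals contribute only this survival term). Because
#' the network and covariates are static, hazards are piecewise constant
#' between events and the integrals are finite sums.
#'
#' The innovator's acquisition is modelled like any other (asocial)
#' event by default; with `innovator_seeded = TRUE` it is conditioned
#' on — the innovator is treated as informed from t = 0 and contributes
#' neither an event nor a survival term.
#'
#' @param data a [diffusion_record()] or a list of them (independent
#'   replicate diffusions; their log-likelihoods add).
#' @param A association matrix.
#' @param covariates per-individual covariate values (model 3).
#' @param params a [parameter_set()].
#' @param innovator_seeded condition on the first acquisition instead of
#'   modelling it.
#' @param ties `"error"` (default) rejects tied event times; `"jitter"`
#'   separates them by `1e-9 * max(time)` with a warning.
#' @return log-likelihood value; `-Inf` if an observed event has zero
#'   hazard under `params` (inconsistent inputs).
#' @export
log_likelihood <- function(data, A, covariates = NULL, params,
                           innovator_seeded = FALSE,
                           ties = c("error", "jitter")) {
  stopifnot(inherits(params, "snbda_params"))
  if (inherits(data, "snbda_diffusion")) data <- list(data)
  ctxs <- lapply(data, diffusion_context, A = A, covariates = covariates,
                 innovator_seeded = innovator_seeded, ties = ties)
  ll_contexts(ctxs, params$model_id, exp(params$log_lambda0),
              if (!is.null(params$log_s_prime)) exp(params$log_s_prime) else 0,
              if (!is.null(params$beta)) params$beta else 0)
}
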