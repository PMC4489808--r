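
# internal state representation used by both samplers: a named list of
# sampling coordinates per model. Under the signed-log parameterisation
# the environmental effect is carried as (log|beta|, sign).

new_trace <- function(draws, model = NULL, burn_in, acceptance, seed,
                      model_ids = NULL, beta_prior = "signed-log") {
  structure(list(draws = draws, model = model, burn_in = burn_in,
                 n_iter = nrow(draws), acceptance = acceptance, seed = seed,
                 model_ids = model_ids, beta_prior = beta_prior),
            class = "snbda_trace")
}

#' @export
print.snbda_trace <- function(x, ...) {
  cat(sprintf("MCMC trace: %d iterations (burn-in %d)%s\n", x$n_iter,
              x$burn_in,
              if (!is.null(x$model)) " with model indicators" else ""))
  invisible(x)
}

in_box <- function(v, lo, hi) all(v >= lo & v <= hi)

# log prior density for the sampling coordinates of a model (uniform box:
# 0 inside, -Inf outside; sign coordinate carries probability 1/2 which is
# constant across models of equal dimension handling and cancels in MH,
# and is included explicitly in RJ jumps via prior draws)
coord_names <- function(model_id, beta_prior) {
  nm <- param_names(model_id)
  if (model_id == 3 && beta_prior == "signed-log")
    nm <- c("log_lambda0", "log_s_prime", "log_beta_mag", "beta_sign")
  nm
}

coords_to_params <- function(coords, model_id, beta_prior, lo, hi, tuning) {
  beta <- NULL
  if (model_id == 3) {
    beta <- if (beta_prior == "signed-log")
      coords[["beta_sign"]] * exp(coords[["log_beta_mag"]])
    else coords[["beta"]]
  }
  parameter_set(model_id, coords[["log_lambda0"]],
                if (model_id >= 2) coords[["log_s_prime"]] else NULL,
                beta, prior_low = lo, prior_high = hi, tuning = tuning,
                beta_prior = beta_prior)
}

coord_in_prior <- function(coords, model_id, beta_prior, lo, hi) {
  nm <- setdiff(names(coords), "beta_sign")
  in_box(unlist(coords[nm]), lo, hi)
}

draw_coords_from_prior <- function(model_id, beta_prior, lo, hi) {
  co <- list(log_lambda0 = stats::runif(1, lo, hi))
  if (model_id >= 2) co$log_s_prime <- stats::runif(1, lo, hi)
  if (model_id == 3) {
    if (beta_prior == "signed-log") {
      co$log_beta_mag <- stats::runif(1, lo, hi)
      co$beta_sign <- sample(c(-1, 1), 1)
    } else {
      co$beta <- stats::runif(1, lo, hi)
    }
  }
  co
}

make_loglik <- function(data, A, covariates, innovator_seeded, ties) {
  if (is.null(data)) return(function(coords, model_id, beta_prior) 0)
  if (inherits(data, "snbda_diffusion")) data <- list(data)
  ctxs <- lapply(data, diffusion_context, A = A, covariates = covariates,
                 innovator_seeded = innovator_seeded, ties = ties)
  function(coords, model_id, beta_prior) {
    beta <- 0
    if (model_id == 3)
      beta <- if (beta_prior == "signed-log")
        coords[["beta_sign"]] * exp(coords[["log_beta_mag"]])
      else coords[["beta"]]
    ll_contexts(ctxs, model_id, exp(coords[["log_lambda0"]]),
                if (model_id >= 2) exp(coords[["log_s_prime"]]) else 0, beta)
  }
}

# one sweep of component-wise uniform random-walk Metropolis updates;
# returns list(coords, ll, accept = named logical)
mh_sweep <- function(coords, model_id, beta_prior, ll_fun, ll_cur,
                     tuning, lo, hi) {
  acc <- logical(0)
  for (nm in setdiff(names(coords), "beta_sign")) {
    eps <- tuning[[component_tuning_name(nm)]]
    prop <- coords
    prop[[nm]] <- coords[[nm]] + stats::runif(1, -eps, eps)
    a <- FALSE
    if (prop[[nm]] >= lo && prop[[nm]] <= hi) {
      ll_prop <- ll_fun(prop, model_id, beta_prior)
      if (is.finite(ll_prop) &&
          log(stats::runif(1)) <= ll_prop - ll_cur) {
        coords <- prop; ll_cur <- ll_prop; a <- TRUE
      }
    }
    acc[nm] <- a
  }
  if ("beta_sign" %in% names(coords)) {
    # independent fresh-sign proposal (symmetric under the even prior);
    # half the proposals keep the current sign, avoiding deterministic
    # alternation
    prop <- coords
    prop$beta_sign <- sample(c(-1, 1), 1)
    ll_prop <- ll_fun(prop, model_id, beta_prior)
    a <- is.finite(ll_prop) && log(stats::runif(1)) <= ll_prop - ll_cur
    if (a) { coords <- prop; ll_cur <- ll_prop }
    acc["beta_sign"] <- a
  }
  list(coords = coords, ll = ll_cur, accept = acc)
}

component_tuning_name <- function(nm) {
  if (nm == "log_beta_mag" || nm == "beta") "beta" else nm
}

#' Within-model Metropolis-Hastings sampler
#'
#' Component-wise uniform random-walk Metropolis on the log-scale
#' parameters of one of the three nested models, targeting
#' prior x likelihood. Each parameter alpha is updated in turn with a
#' proposal drawn from `U[alpha - eps, alpha + eps]`; proposals outside
#' the prior box are rejected. With `data = NULL` the likelihood is
#' switched off and the sampler targets the prior alone (useful as a
#' correctness diagnostic).
#'
#' @param model_id 1, 2 or 3.
#' @param data a [diffusion_record()], a list of them, or `NULL` for a
#'   prior-only run.
#' @param A association matrix (ignored when `data = NULL`).
#' @param covariates per-individual covariates (model 3).
#' @param params0 optional [parameter_set()] giving the initial state;
#'   defaults to a draw from the prior. Must lie inside the prior
#'   support.
#' @param n_iter total iterations (sweeps).
#' @param burn_in iterations discarded by [posterior_summary()].
#' @param tuning named proposal half-widths; defaults
#'   `c(log_lambda0 = 1, log_s_prime = 1, beta = 3)`.
#' @param thin keep every `thin`-th sweep (after the first); total
#'   sweeps performed = `n_iter * thin`.
#' @param seed integer seed; identical seeds give identical traces.
#' @param prior_low,prior_high prior box bounds.
#' @param beta_prior `"signed-log"` or `"uniform"` (see
#'   [parameter_set()]).
#' @param innovator_seeded,ties passed to the likelihood; see
#'   [log_likelihood()].
#' @return an object of class `"snbda_trace"`: retained draws (matrix
#'   with one column per parameter, environmental effect reported as
#'   signed `beta`), burn-in, per-parameter acceptance rates, seed.
#' @export
mh_sample <- function(model_id, data = NULL, A = NULL, covariates = NULL,
                      params0 = NULL, n_iter = 20000, burn_in = 2000,
                      tuning = NULL, thin = 1, seed = 1,
                      prior_low = -10, prior_high = 10,
                      beta_prior = c("signed-log", "uniform"),
                      innovator_seeded = FALSE, ties = "error") {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3")
  beta_prior <- match.arg(beta_prior)
  if (n_iter < 1) stop("n_iter must be at least 1")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  tun <- c(log_lambda0 = 1, log_s_prime = 1, beta = 3)
  if (!is.null(tuning)) {
    if (any(tuning <= 0)) stop("tuning widths must be positive")
    tun[names(tuning)] <- tuning
  }
  set.seed(seed)
  lo <- prior_low; hi <- prior_high
  ll_fun <- make_loglik(data, A, covariates, innovator_seeded, ties)
  coords <- if (is.null(params0)) {
    # retry prior draws that land where the likelihood underflows to zero
    co <- draw_coords_from_prior(model_id, beta_prior, lo, hi)
    for (try in 1:200) {
      if (is.finite(ll_fun(co, model_id, beta_prior))) break
      co <- draw_coords_from_prior(model_id, beta_prior, lo, hi)
    }
    co
  } else {
    stopifnot(inherits(params0, "snbda_params"))
    if (params0$model_id != model_id) stop("params0 model does not match model_id")
    if (!is.finite(log_prior(params0)))
      stop("initial parameters lie outside the prior support")
    co <- list(log_lambda0 = params0$log_lambda0)
    if (model_id >= 2) co$log_s_prime <- params0$log_s_prime
    if (model_id == 3) {
      if (beta_prior == "signed-log") {
        co$log_beta_mag <- log(abs(params0$beta))
        co$beta_sign <- sign(params0$beta)
      } else co$beta <- params0$beta
    }
    co
  }
  ll_cur <- ll_fun(coords, model_id, beta_prior)
  if (!is.finite(ll_cur))
    stop("initial parameters have zero likelihood; choose another start")
  out_names <- param_names(model_id)
  draws <- matrix(NA_real_, n_iter, length(out_names),
                  dimnames = list(NULL, out_names))
  acc_tot <- NULL
  n_sweeps <- 0L
  for (it in seq_len(n_iter)) {
    for (s in seq_len(thin)) {
      step <- mh_sweep(coords, model_id, beta_prior, ll_fun, ll_cur,
                       tun, lo, hi)
      coords <- step$coords; ll_cur <- step$ll
      acc_tot <- if (is.null(acc_tot)) step$accept + 0 else acc_tot + step$accept
      n_sweeps <- n_sweeps + 1L
    }
    draws[it, "log_lambda0"] <- coords$log_lambda0
    if (model_id >= 2) draws[it, "log_s_prime"] <- coords$log_s_prime
    if (model_id == 3)
      draws[it, "beta"] <- if (beta_prior == "signed-log")
        coords$beta_sign * exp(coords$log_beta_mag) else coords$beta
  }
  new_trace(draws, model = NULL, burn_in = burn_in,
            acceptance = acc_tot / n_sweeps, seed = seed,
            beta_prior = beta_prior)
}

#' Reversible-jump MCMC across the nested models
#'
#' Treats the model indicator as an additional parameter and samples
#' jointly over models and parameters. Each iteration performs one
#' within-model Metropolis sweep; with probability `move_prob` a
#' between-model jump is then attempted: a different model is proposed
#' uniformly, parameters shared with the current model are carried
#' over, and parameters absent from it are drawn from their priors
#' (Jacobian 1), so the acceptance probability reduces to the
#' likelihood ratio under the uniform model prior. Posterior model
#' probabilities are the retained-visit fractions.
#'
#' @inheritParams mh_sample
#' @param model_ids subset of `1:3`, at least two models.
#' @param move_prob probability of attempting a between-model jump at
#'   each iteration (default 0.5).
#' @return `"snbda_trace"` with a `model` indicator vector alongside
#'   the draws (parameters not in the current model are `NA`).
#' @export
rjmcmc_sample <- function(model_ids = 1:3, data = NULL, A = NULL,
                          covariates = NULL, n_iter = 20000,
                          burn_in = 2000, tuning = NULL, move_prob = 0.5,
                          seed = 1, prior_low = -10, prior_high = 10,
                          beta_prior = c("signed-log", "uniform"),
                          innovator_seeded = FALSE, ties = "error") {
  model_ids <- sort(unique(as.integer(model_ids)))
  if (length(model_ids) < 2 || !all(model_ids %in% 1:3))
    stop("model_ids must contain at least two of 1, 2, 3")
  beta_prior <- match.arg(beta_prior)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  tun <- c(log_lambda0 = 1, log_s_prime = 1, beta = 3)
  if (!is.null(tuning)) {
    if (any(tuning <= 0)) stop("tuning widths must be positive")
    tun[names(tuning)] <- tuning
  }
  set.seed(seed)
  lo <- prior_low; hi <- prior_high
  ll_fun <- make_loglik(data, A, covariates, innovator_seeded, ties)
  model <- model_ids[1]
  coords <- draw_coords_from_prior(model, beta_prior, lo, hi)
  for (try in 1:200) {
    if (is.finite(ll_fun(coords, model, beta_prior))) break
    coords <- draw_coords_from_prior(model, beta_prior, lo, hi)
  }
  ll_cur <- ll_fun(coords, model, beta_prior)
  if (!is.finite(ll_cur))
    stop("could not find a starting point with positive likelihood")
  draws <- matrix(NA_real_, n_iter, 3,
                  dimnames = list(NULL, c("log_lambda0", "log_s_prime", "beta")))
  model_trace <- integer(n_iter)
  acc_within <- 0; n_within <- 0; acc_jump <- 0; n_jump <- 0
  for (it in seq_len(n_iter)) {
    step <- mh_sweep(coords, model, beta_prior, ll_fun, ll_cur, tun, lo, hi)
    coords <- step$coords; ll_cur <- step$ll
    acc_within <- acc_within + mean(step$accept); n_within <- n_within + 1
    if (stats::runif(1) < move_prob) {
      others <- setdiff(model_ids, model)
      prop_model <- if (length(others) == 1) others else
        others[sample.int(length(others), 1)]
      prop <- carry_coords(coords, model, prop_model, beta_prior, lo, hi)
      ll_prop <- ll_fun(prop, prop_model, beta_prior)
      n_jump <- n_jump + 1
      # prior-draw proposals for birthed coordinates cancel with their
      # prior densities; uniform model prior and symmetric model proposal
      # leave the likelihood ratio
      if (is.finite(ll_prop) && log(stats::runif(1)) <= ll_prop - ll_cur) {
        model <- prop_model; coords <- prop; ll_cur <- ll_prop
        acc_jump <- acc_jump + 1
      }
    }
    model_trace[it] <- model
    draws[it, "log_lambda0"] <- coords$log_lambda0
    if (model >= 2) draws[it, "log_s_prime"] <- coords$log_s_prime
    if (model == 3)
      draws[it, "beta"] <- if (beta_prior == "signed-log")
        coords$beta_sign * exp(coords$log_beta_mag) else coords$beta
  }
  new_trace(draws, model = model_trace, burn_in = burn_in,
            acceptance = c(within = acc_within / n_within,
                           jump = if (n_jump > 0) acc_jump / n_jump else NA),
            seed = seed, model_ids = model_ids, beta_prior = beta_prior)
}

carry_coords <- function(coords, from, to, beta_prior, lo, hi) {
  keep <- intersect(coord_names(from, beta_prior), coord_names(to, beta_prior))
  prop <- coords[keep]
  born <- setdiff(coord_names(to, beta_prior), keep)
  for (nm in born) {
    prop[[nm]] <- if (nm == "beta_sign") sample(c(-1, 1), 1)
                  else stats::runif(1, lo, hi)
  }
  prop
}

#' Posterior summaries of an MCMC trace
#'
#' Post burn-in means and symmetric 95% credible intervals (2.5% and
#' 97.5% quantiles, linear interpolation of order statistics — R's
#' default quantile rule) for each parameter, on the natural-log scale
#' for the rates and as a signed value for the environmental effect.
#' For reversible-jump traces, model probabilities are the retained
#' visit fractions and parameter summaries are conditional on the
#' visits to each model.
#'
#' @param trace an `"snbda_trace"` from [mh_sample()] or
#'   [rjmcmc_sample()].
#' @param burn_in override for the trace's stored burn-in.
#' @return list with `parameters` (data frame: parameter, and for RJ
#'   traces model, mean, low, high, n) and, for RJ traces,
#'   `model_probabilities` (named vector summing to 1) and
#'   `model_counts`.
#' @export
posterior_summary <- function(trace, burn_in = NULL) {
  stopifnot(inherits(trace, "snbda_trace"))
  if (is.null(burn_in)) burn_in <- trace$burn_in
  if (burn_in >= trace$n_iter) stop("burn_in leaves no retained draws")
  idx <- (burn_in + 1L):trace$n_iter
  draws <- trace$draws[idx, , drop = FALSE]
  summarise <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA, low = NA, high = NA, n = 0))
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    c(mean = mean(v), low = q[1], high = q[2], n = length(v))
  }
  if (is.null(trace$model)) {
    tab <- t(apply(draws, 2, summarise))
    out <- data.frame(parameter = colnames(draws), tab, row.names = NULL)
    return(list(parameters = out))
  }
  models <- trace$model[idx]
  counts <- table(factor(models, levels = trace$model_ids))
  probs <- as.numeric(counts) / length(models)
  names(probs) <- names(counts)
  rows <- list()
  for (m in trace$model_ids) {
    sel <- models == m
    if (!any(sel)) next
    for (p in param_names(m)) {
      s <- summarise(draws[sel, p])
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, parameter = p, mean = s["mean"], low = s["low"],
        high = s["high"], n = s["n"], row.names = NULL)
    }
  }
  list(parameters = do.call(rbind, rows),
       model_probabilities = probs,
       model_counts = as.integer(counts))
}

#' Bayes factor from reversible-jump visit counts
#'
#' Under a uniform prior over models, the posterior odds of two models
#' equal the Bayes factor, estimated by the ratio of retained visit
#' counts. Accepts either an RJ trace or a named vector/list of visit
#' counts directly.
#'
#' @param trace an RJ `"snbda_trace"`, or a numeric vector of visit
#'   counts named by model id.
#' @param model_a,model_b model identifiers to compare (a over b).
#' @param burn_in override for the trace's stored burn-in.
#' @return positive Bayes factor; `Inf` (with a warning) when model_b
#'   was never visited.
#' @export
bayes_factor <- function(trace, model_a, model_b, burn_in = NULL) {
  if (inherits(trace, "snbda_trace")) {
    if (is.null(trace$model)) stop("trace carries no model indicators")
    if (is.null(burn_in)) burn_in <- trace$burn_in
    idx <- (burn_in + 1L):trace$n_iter
    counts <- table(trace$model[idx])
    ca <- counts[as.character(model_a)]
    cb <- counts[as.character(model_b)]
    ca <- if (is.na(ca)) 0 else as.numeric(ca)
    cb <- if (is.na(cb)) 0 else as.numeric(cb)
  } else {
    counts <- unlist(trace)
    nm <- names(counts)
    if (is.null(nm)) stop("counts must be named by model id")
    ca <- counts[[as.character(model_a)]]
    cb <- counts[[as.character(model_b)]]
  }
  if (ca < 1) warning("model_a was never visited; Bayes factor is 0")
  if (cb < 1) {
    warning("model_b was never visited; Bayes factor reported as Inf")
    return(Inf)
  }
  ca / cb
}
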