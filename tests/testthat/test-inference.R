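test_that("posterior summaries follow the documented quantile rule", {
  mk <- function(v) snbda:::new_trace(matrix(v, ncol = 1,
                                             dimnames = list(NULL, "log_lambda0")),
                                      burn_in = 0, acceptance = 1, seed = 1)
  # constant trace: degenerate interval
  s <- posterior_summary(mk(rep(2.5, 50)))$parameters
  expect_equal(s$mean, 2.5)
  expect_equal(s$low, 2.5)
  expect_equal(s$high, 2.5)
  # retained draws 1..100: mean 50.5, interval by linear interpolation of
  # order statistics (R's default rule)
  s2 <- posterior_summary(mk(as.numeric(1:100)))$parameters
  expect_equal(s2$mean, 50.5)
  expect_equal(s2$low, 3.475)
  expect_equal(s2$high, 97.525)
  # burn-in all but one draw: single-draw summary
  tr <- mk(as.numeric(1:100)); tr$burn_in <- 99
  s3 <- posterior_summary(tr)$parameters
  expect_equal(s3$mean, 100)
  expect_equal(s3$low, 100)
  expect_equal(s3$n, 1)
  expect_error(posterior_summary(tr, burn_in = 100), "retained")
})

test_that("Bayes factors are visit-count ratios", {
  # the reported three-model comparison: 11172 vs 6829 retained visits
  expect_equal(round(bayes_factor(c(`2` = 11172, `3` = 6829), 2, 3), 2), 1.64)
  expect_equal(bayes_factor(c(`1` = 77, `2` = 77), 1, 2), 1)
  expect_equal(bayes_factor(c(`1` = 100, `2` = 50), 1, 2), 2)
  expect_warning(bf <- bayes_factor(c(`1` = 100, `2` = 0), 1, 2), "Inf")
  expect_identical(bf, Inf)
})

test_that("MH traces are reproducible and respect their inputs", {
  st <- simulate_study(seed = 41, n_diffusions = 2)
  f1 <- mh_sample(2, st$diffusions, st$A, n_iter = 400, burn_in = 100, seed = 7)
  f2 <- mh_sample(2, st$diffusions, st$A, n_iter = 400, burn_in = 100, seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws >= -10 & f1$draws <= 10))
  expect_named(f1$acceptance, c("log_lambda0", "log_s_prime"))
  expect_error(mh_sample(2, st$diffusions, st$A, n_iter = 100, burn_in = 100),
               "burn_in")
  expect_error(mh_sample(2, st$diffusions, st$A,
                         params0 = parameter_set(1, 0)), "model")
  # a vanishing proposal width leaves the chain essentially immobile
  f3 <- mh_sample(2, st$diffusions, st$A, n_iter = 200, burn_in = 0,
                  tuning = c(log_lambda0 = 1e-12, log_s_prime = 1e-12),
                  seed = 8)
  expect_lt(max(apply(f3$draws, 2, sd)), 1e-9)
})

test_that("prior-only MH recovers the uniform box prior", {
  # wide proposals plus thinning give near-independent draws so the KS
  # test applies
  tr <- mh_sample(2, data = NULL, n_iter = 1500, burn_in = 100,
                  tuning = c(log_lambda0 = 10, log_s_prime = 10),
                  thin = 10, seed = 13)
  keep <- tr$draws[101:1500, ]
  expect_gt(ks.test(keep[, "log_lambda0"], "punif", -10, 10)$p.value, 0.001)
  expect_gt(ks.test(keep[, "log_s_prime"], "punif", -10, 10)$p.value, 0.001)
  # model 3: the signed-log parameterisation returns U(-10,10) magnitudes
  # and an even sign
  tr3 <- mh_sample(3, data = NULL, n_iter = 1500, burn_in = 100,
                   tuning = c(log_lambda0 = 10, log_s_prime = 10, beta = 10),
                   thin = 10, seed = 14)
  b <- tr3$draws[101:1500, "beta"]
  expect_gt(ks.test(log(abs(b)), "punif", -10, 10)$p.value, 0.001)
  expect_gt(binom.test(sum(b > 0), length(b))$p.value, 0.001)
})

test_that("flat-likelihood RJMCMC visits models uniformly", {
  rj <- rjmcmc_sample(1:3, data = NULL, n_iter = 20000, burn_in = 1000,
                      seed = 15)
  probs <- posterior_summary(rj)$model_probabilities
  expect_equal(sum(probs), 1)
  expect_true(all(abs(probs - 1 / 3) < 0.1))
  # determinism
  rj2 <- rjmcmc_sample(1:3, data = NULL, n_iter = 2000, burn_in = 100, seed = 16)
  rj3 <- rjmcmc_sample(1:3, data = NULL, n_iter = 2000, burn_in = 100, seed = 16)
  expect_identical(rj2$model, rj3$model)
  expect_identical(rj2$draws, rj3$draws)
  expect_error(rjmcmc_sample(2, data = NULL), "at least two")
})

test_that("posteriors concentrate on the generating model and parameters", {
  st <- simulate_study(seed = 47)
  fit <- mh_sample(2, st$diffusions, st$A, n_iter = 3000, burn_in = 500,
                   seed = 17)
  s <- posterior_summary(fit)$parameters
  ll0 <- s[s$parameter == "log_lambda0", ]
  lsp <- s[s$parameter == "log_s_prime", ]
  expect_true(ll0$low < -1.6 && -1.6 < ll0$high)
  expect_true(lsp$low < 0.84 && 0.84 < lsp$high)

  rj <- rjmcmc_sample(1:3, st$diffusions, st$A, covariates = st$covariates,
                      n_iter = 4000, burn_in = 500, seed = 18)
  sum_rj <- posterior_summary(rj)
  expect_lt(sum_rj$model_probabilities[["1"]], 0.05)
  # model selection sharpens with more data: joint support for the
  # social models stays overwhelming
  expect_gt(sum_rj$model_probabilities[["2"]] +
            sum_rj$model_probabilities[["3"]], 0.9)
})
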