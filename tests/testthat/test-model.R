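test_that("hazard follows the social-transmission rate specification", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 0.5
  p1 <- parameter_set(1, log_lambda0 = log(1))
  p2 <- parameter_set(2, log_lambda0 = log(1), log_s_prime = log(2))
  # informed individuals have zero rate
  expect_equal(hazard(2, c(FALSE, TRUE, FALSE), p2, A), 0)
  # null model: bare baseline rate
  expect_equal(hazard(1, rep(FALSE, 3), p1, A), 1)
  # lambda0 = 1, s' = 2, one informed neighbour with a = 0.5: rate 2
  expect_equal(hazard(1, c(FALSE, TRUE, FALSE), p2, A), 2)
  # model 3 scales the asocial part by exp(beta * c)
  p3 <- parameter_set(3, log_lambda0 = log(1), log_s_prime = log(2),
                      beta = 0.5)
  expect_equal(hazard(1, c(FALSE, TRUE, FALSE), p3, A, covariates = c(2, 0, 0)),
               2 * 0.5 + exp(1))
  expect_error(hazard(1, c(FALSE, TRUE, FALSE), p3, A, covariates = c(NA, 0, 0)),
               "covariates")
})

test_that("the s and s-prime parameterisations give identical hazards", {
  # s' = lambda0 * s: lambda0 (s * sum a z + 1) == s' * sum a z + lambda0
  A <- matrix(runif(16), 4, 4); diag(A) <- 0
  lambda0 <- 0.7; s <- 3.2
  pr <- parameter_set(2, log_lambda0 = log(lambda0),
                      log_s_prime = log(lambda0 * s))
  z <- c(TRUE, FALSE, TRUE, FALSE)
  for (i in which(!z)) {
    expect_equal(hazard(i, z, pr, A),
                 lambda0 * (s * sum(A[i, z]) + 1), tolerance = 1e-12)
  }
})

test_that("single-individual likelihood is the exponential log-density", {
  rec <- diffusion_record("a", 1.7)
  A <- matrix(0, 1, 1, dimnames = list("a", "a"))
  p <- parameter_set(1, log_lambda0 = log(0.8))
  expect_equal(log_likelihood(rec, A, params = p),
               log(0.8) - 0.8 * 1.7, tolerance = 1e-12)
})

test_that("an empty network makes the social term inert", {
  set.seed(31)
  rec <- diffusion_record(1:6, cumsum(rexp(6)))
  A <- matrix(0, 6, 6)
  p1 <- parameter_set(1, log_lambda0 = -0.5)
  for (ls in c(-3, 0, 4)) {
    p2 <- parameter_set(2, log_lambda0 = -0.5, log_s_prime = ls)
    expect_equal(log_likelihood(rec, A, params = p2),
                 log_likelihood(rec, A, params = p1), tolerance = 1e-12)
  }
})

test_that("likelihood matches the hazard-path oracle on worked cases", {
  A <- matrix(c(0, 0.4, 0.1,
                0.3, 0, 0.6,
                0.2, 0.5, 0), 3, 3, byrow = TRUE)
  cv <- c(-0.8, 0.2, 1.1)
  rec <- diffusion_record(1:3, c(0.5, 1.2, 2.0))
  for (p in list(parameter_set(1, log_lambda0 = -0.3),
                 parameter_set(2, log_lambda0 = -0.3, log_s_prime = 0.7),
                 parameter_set(3, log_lambda0 = -0.3, log_s_prime = 0.7,
                               beta = -1.2))) {
    expect_equal(log_likelihood(rec, A, covariates = cv, params = p),
                 loglik_hazard_oracle(rec, A, cv, p), tolerance = 1e-8)
  }
  # censored case against the same oracle
  recc <- diffusion_record(1:3, c(0.5, 1.2, NA), horizon = 3)
  p2 <- parameter_set(2, log_lambda0 = -0.3, log_s_prime = 0.7)
  expect_equal(log_likelihood(recc, A, params = p2),
               loglik_hazard_oracle(recc, A, NULL, p2), tolerance = 1e-8)
  # replicate diffusions add
  expect_equal(log_likelihood(list(rec, rec), A, covariates = cv,
                              params = p2),
               2 * log_likelihood(rec, A, covariates = cv, params = p2),
               tolerance = 1e-12)
})

test_that("asocial likelihood is maximised at the closed-form exponential MLE", {
  set.seed(37)
  n <- 25
  tt <- rexp(n, 1.3)
  rec <- diffusion_record(1:n, tt)
  A <- matrix(0, n, n)
  obj <- function(ll0) log_likelihood(rec, A, params = parameter_set(1, ll0))
  opt <- optimize(obj, c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(exp(opt$maximum), n / sum(tt), tolerance = 1e-6)
})

test_that("seeded innovators are conditioned out of the likelihood", {
  n <- 4
  tt <- c(0.3, 0.9, 1.4, 2.2)
  rec <- diffusion_record(1:n, tt)
  A <- matrix(0, n, n)
  lambda0 <- 0.6
  p <- parameter_set(1, log_lambda0 = log(lambda0))
  # asocial, empty network: seeded innovator contributes neither event
  # nor survival; everyone else is exponential from t = 0
  expected <- sum(log(lambda0) - lambda0 * tt[-1])
  expect_equal(log_likelihood(rec, A, params = p, innovator_seeded = TRUE),
               expected, tolerance = 1e-12)
})

test_that("tied event times are rejected or jittered as configured", {
  rec <- diffusion_record(1:3, c(0.5, 0.5, 1))
  A <- matrix(0, 3, 3)
  p <- parameter_set(1, 0)
  expect_error(log_likelihood(rec, A, params = p), "tied")
  expect_warning(ll <- log_likelihood(rec, A, params = p, ties = "jitter"),
                 "jitter")
  expect_true(is.finite(ll))
})

test_that("box priors are flat inside and impossible outside", {
  expect_equal(log_prior(parameter_set(3, 0, 0, beta = 1)), 0)
  expect_equal(log_prior(parameter_set(1, 11)), -Inf)
  # closed-interval convention at the boundary
  expect_equal(log_prior(parameter_set(1, 10)), 0)
  expect_equal(log_prior(parameter_set(2, 0, -10)), 0)
  # signed-log prior constrains the magnitude of beta
  expect_equal(log_prior(parameter_set(3, 0, 0, beta = -exp(9.9))), 0)
  expect_equal(log_prior(parameter_set(3, 0, 0, beta = exp(10.1))), -Inf)
  # uniform alternative constrains beta directly
  expect_equal(log_prior(parameter_set(3, 0, 0, beta = exp(2),
                                       beta_prior = "uniform")), 0)
  expect_equal(log_prior(parameter_set(3, 0, 0, beta = 10.5,
                                       beta_prior = "uniform")), -Inf)
})

test_that("parameter sets enforce the nested model structure", {
  expect_error(parameter_set(2, 0), "log_s_prime")
  expect_error(parameter_set(3, 0, 0), "beta")
  expect_error(parameter_set(4, 0), "model_id")
  p1 <- parameter_set(1, 0, log_s_prime = 3, beta = 2)
  expect_null(p1$log_s_prime)
  expect_null(p1$beta)
})
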