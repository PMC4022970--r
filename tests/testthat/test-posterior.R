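# Censored log-likelihood, priors and the monitored log-posterior.

one_obs <- function(status) survival_data(time = 1, status = status)

test_that("single-observation likelihood reduces to the standard forms", {
  # y = 0, mu = 0, sigma = 1, k = 1: density 1/4, survivor 1/2
  expect_equal(logburr_loglik(c(0, 0), one_obs(1), k = 1), log(1 / 4),
               tolerance = 1e-12)
  expect_equal(logburr_loglik(c(0, 0), one_obs(0), k = 1), log(1 / 2),
               tolerance = 1e-12)
  expect_equal(logburr_deviance(c(0, 0), one_obs(1), k = 1),
               2 * 1.3862944, tolerance = 1e-6)
  expect_equal(logburr_deviance(c(0, 0), one_obs(0), k = 1),
               1.3862944, tolerance = 1e-6)
})

test_that("likelihood matches a term-by-term oracle on a toy data set", {
  d <- survival_data(time = exp(c(0, 0.5, 1)), status = c(1, 1, 0))
  beta <- 0.2; log_sigma <- -0.1; k <- 30
  sigma <- exp(log_sigma)
  z <- (c(0, 0.5, 1) - beta) / sigma
  # direct evaluation of the stated formulas, term by term
  oracle <- sum(
    (z[1:2] - (k + 1) * log(1 + exp(z[1:2]) / k)) - log_sigma) +
    (-k * log(1 + exp(z[3]) / k))
  expect_equal(logburr_loglik(c(beta, log_sigma), d, k), oracle,
               tolerance = 1e-10)
  expect_equal(logburr_deviance(c(beta, log_sigma), d, k), -2 * oracle,
               tolerance = 1e-10)
  # vectorized path agrees with the scalar path
  theta <- rbind(c(beta, log_sigma), c(0, 0), c(1, 0.3))
  expect_equal(logburr:::loglik_many(theta, d, k),
               apply(theta, 1, logburr_loglik, data = d, k = k),
               tolerance = 1e-12)
})

test_that("model evaluation carries LP, deviance and monitors coherently", {
  model <- logburr_model("logistic")
  params <- c(5, -0.9)
  ev <- logburr_logpost(params, loco, model)
  ll <- logburr_loglik(params, loco, 1)
  expect_equal(ev$Dev, -2 * ll)
  # LP minus the likelihood equals the prior log density exactly
  prior <- stats::dnorm(5, 0, 1000, log = TRUE) +
    dhalfcauchy(exp(-0.9), 25, log = TRUE)
  expect_equal(ev$LP - ll, prior, tolerance = 1e-12)
  expect_equal(unname(ev$monitors["LP"]), ev$LP)
  expect_equal(unname(ev$monitors["sigma"]), exp(-0.9))
  expect_equal(ev$yhat, rep(5, 96))
})

test_that("zero-data posterior is the prior alone", {
  # one censored observation at an enormous time contributes ~0 to the
  # likelihood only asymptotically, so build the N = 0 case directly
  d0 <- survival_data(time = numeric(0), status = numeric(0))
  ev <- logburr_logpost(c(0, 0), d0, logburr_model(k = 1))
  expect_equal(ev$LP, stats::dnorm(0, 0, 1000, log = TRUE) +
                 dhalfcauchy(1, 25, log = TRUE), tolerance = 1e-12)
  expect_equal(ev$Dev, 0)
})

test_that("likelihood is location and scale equivariant", {
  params <- c(5.1, -0.8)
  base <- logburr_loglik(params, loco, 1)
  # shifting y and the intercept by the same constant changes nothing
  shifted <- survival_data(loco$time * exp(2), loco$delta)
  expect_equal(logburr_loglik(c(5.1 + 2, -0.8), shifted, 1), base,
               tolerance = 1e-10)
  # scaling the residuals and sigma by b shifts LL by -(#events) log b
  b <- 1.7
  scaled <- survival_data(exp(5.1 + b * (loco$y - 5.1)), loco$delta)
  expect_equal(logburr_loglik(c(5.1, -0.8 + log(b)), scaled, 1),
               base - sum(loco$delta) * log(b), tolerance = 1e-8)
})

test_that("fully censored data sees only the survivor term", {
  d <- survival_data(loco$time, rep(0, 96))
  # survivor terms increase monotonically in mu, with no density bound
  lls <- vapply(seq(4, 9, by = 0.5),
                function(m) logburr_loglik(c(m, -0.9), d, 1), numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_equal(max(lls), lls[length(lls)])
})

test_that("LP at the published posterior means reconciles the prior stack", {
  # frozen independent evaluation: loglik at (5.09, -0.93) on the
  # locomotive data is -73.616, the weak priors add -11.497
  ev <- logburr_logpost(c(5.09, -0.93), loco, logburr_model("logistic"))
  expect_equal(ev$LP, -85.11323, tolerance = 1e-4)
  expect_equal(ev$Dev, 147.2316, tolerance = 1e-3)
  prior <- ev$LP + ev$Dev / 2
  expect_equal(prior, -11.49742, tolerance = 1e-4)
})

test_that("model aliases and validation behave", {
  expect_equal(logburr_model("logistic")$k, 1)
  expect_equal(logburr_model("weibull")$k, 30)
  expect_equal(logburr_model("infinity")$k, Inf)
  expect_error(logburr_model("gamma"), "alias")
  expect_error(logburr_model(k = 1, beta_prior_sd = -1), "positive")
  expect_error(logburr_loglik(c(1, 2, 3), loco, 1), "length")
})
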