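# Shared fixtures: the Laplace fits of the locomotive data are reused
# across test files (they are deterministic, so computing them once is
# safe and keeps the suite fast).

loco <- locomotive_data()
fit_logistic <- fit_laplace(loco, logburr_model("logistic"))
fit_weibull <- fit_laplace(loco, logburr_model("weibull"))

# gaussian log-density helper for injected targets
mvn_logpdf <- function(x, mean, cov) {
  d <- length(mean)
  U <- chol(cov)
  w <- backsolve(U, x - mean, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + sum(w^2))
}

# a laplace_fit-shaped object for injected proposal tests
fake_fit <- function(mode, cov, lpfun) {
  structure(list(mode = mode, covariance = cov, lp = lpfun(mode),
                 converged = TRUE, iterations = 0L, method = "injected",
                 gradient = rep(0, length(mode)), lpfun = lpfun,
                 data = NULL, model = NULL),
            class = "laplace_fit")
}
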