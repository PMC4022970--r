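# Standardized log-Burr distribution functions and the half-Cauchy prior.

test_that("logistic special case k = 1 matches the closed forms exactly", {
  z <- c(-30, -5, -1, 0, 0.5, 3, 30)
  expect_equal(dlogburr(z, k = 1), stats::dlogis(z), tolerance = 1e-14)
  expect_equal(plogburr(z, k = 1), stats::plogis(z), tolerance = 1e-14)
  expect_equal(plogburr(z, k = 1, lower.tail = FALSE),
               stats::plogis(z, lower.tail = FALSE), tolerance = 1e-14)
  expect_identical(dlogburr(0, k = 1, log = TRUE), log(1 / 4))
  expect_identical(plogburr(0, k = 1), 0.5)
})

test_that("extreme-value limit k = Inf and finite-k values are correct", {
  # closed forms at z = 0
  expect_equal(dlogburr(0, k = Inf, log = TRUE), -1)
  expect_equal(plogburr(0, k = Inf), 1 - exp(-1), tolerance = 1e-14)
  # frozen high-precision evaluations of the closed forms at k = 30:
  # -31 log(31/30) and (31/30)^-30
  expect_equal(dlogburr(0, k = 30, log = TRUE), -1.01648450,
               tolerance = 1e-7)
  expect_equal(plogburr(0, k = 30, lower.tail = FALSE), 0.37392702,
               tolerance = 1e-7)
  # large finite k approaches the extreme-value functions
  z <- seq(-5, 2, length.out = 40)
  expect_lt(max(abs(plogburr(z, k = 1e6, lower.tail = FALSE) -
                      exp(-exp(z)))), 1e-5)
})

test_that("tails are evaluated stably far from the center", {
  expect_equal(plogburr(-50, k = 1, lower.tail = FALSE), 1,
               tolerance = 1e-15)
  # the cdf deep in the left tail is exp(z) to first order, not 0
  expect_equal(plogburr(-50, k = 1), exp(-50), tolerance = 1e-6)
  expect_equal(plogburr(-700, k = 30), 30 * exp(-700) / 30,
               tolerance = 1e-4)
  # log-density stays finite out to |z| = 700
  for (k in c(0.5, 1, 30, Inf)) {
    expect_true(all(is.finite(dlogburr(c(-700, 700), k, log = TRUE))))
  }
})

test_that("density integrates to one and is consistent with the survivor", {
  for (k in c(0.5, 1, 10, 30)) {
    # small k has a heavy right tail, so integrate the whole line
    total <- stats::integrate(function(z) dlogburr(z, k), -Inf, Inf,
                              rel.tol = 1e-12)$value
    expect_equal(total, 1, tolerance = 1e-8)
    # -d/dz R0(z) = f0(z) by central difference
    z <- seq(-6, 3, length.out = 20)
    h <- 1e-5
    deriv <- -(plogburr(z + h, k, lower.tail = FALSE) -
                 plogburr(z - h, k, lower.tail = FALSE)) / (2 * h)
    expect_equal(deriv, dlogburr(z, k), tolerance = 1e-6)
  }
})

test_that("quantile function inverts the cdf", {
  expect_equal(qlogburr(0.5, k = 1), 0, tolerance = 1e-14)
  expect_equal(qlogburr(1 - exp(-1), k = Inf), 0, tolerance = 1e-12)
  # bisection oracle for one non-trivial case
  bisect <- function(p, k) {
    lo <- -50; hi <- 50
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (plogburr(mid, k) < p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(qlogburr(0.975, k = 30), bisect(0.975, 30),
               tolerance = 1e-10)
  # round trip over a grid of probabilities and shapes
  for (k in c(0.5, 1, 30, Inf)) {
    p <- c(1e-6, 0.025, 0.3, 0.5, 0.9, 0.999)
    expect_equal(plogburr(qlogburr(p, k), k), p, tolerance = 1e-10)
  }
})

test_that("inversion sampling has the right law and is deterministic", {
  x <- rlogburr(10000, k = 1, seed = 42)
  expect_equal(mean(x <= 0), 0.5, tolerance = 0.015)
  x30 <- rlogburr(10000, k = 30, seed = 42)
  expect_equal(mean(x30 > 0), plogburr(0, 30, lower.tail = FALSE),
               tolerance = 0.015)
  expect_identical(rlogburr(5, k = 1, seed = 7), rlogburr(5, k = 1, seed = 7))
})

test_that("domain violations error", {
  expect_error(dlogburr(0, k = 0), "positive")
  expect_error(plogburr(0, k = -2), "positive")
  expect_error(qlogburr(0, k = 1), "inside")
  expect_error(qlogburr(1, k = 1), "inside")
  expect_error(dhalfcauchy(-1), "support")
  expect_error(dhalfcauchy(1, scale = 0), "positive")
})

test_that("half-Cauchy density has the right values and mass", {
  expect_equal(dhalfcauchy(0, 25, log = TRUE), log(2 / (25 * pi)),
               tolerance = 1e-12)
  expect_equal(dhalfcauchy(25, 25, log = TRUE),
               dhalfcauchy(0, 25, log = TRUE) - log(2), tolerance = 1e-12)
  expect_equal(dhalfcauchy(1, 1, log = TRUE), log(1 / pi),
               tolerance = 1e-12)
  # mass: numeric head over [0, 1e3 * scale] plus the analytic Cauchy
  # tail 1 - (2/pi) atan(1e3)
  for (scale in c(1, 25)) {
    head <- stats::integrate(dhalfcauchy, 0, 1e3 * scale, scale = scale,
                             rel.tol = 1e-12, subdivisions = 1000L)$value
    tail <- 1 - 2 / pi * atan(1e3)
    expect_equal(head + tail, 1, tolerance = 1e-8)
  }
})
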