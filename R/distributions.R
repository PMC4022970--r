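# Standardized generalized log-Burr distribution and the half-Cauchy prior.
#
# The log-Burr family is a location-scale family for y = log(t): the
# standardized variable z = (y - mu)/sigma has survivor function
# (1 + e^z / k)^(-k) with shape k > 0.  k = 1 is the logistic distribution
# (log-logistic lifetimes); k -> Inf is the extreme-value distribution
# (Weibull lifetimes).  All evaluation is done in log space so that the
# far tails needed by censored likelihoods do not overflow.

check_shape <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) ||
      (!is.infinite(k) && k <= 0)) {
    stop("shape `k` must be a single positive number or Inf", call. = FALSE)
  }
  k
}

# log(1 + exp(x)) without overflow/underflow (piecewise evaluation)
log1pexp <- function(x) {
  out <- x
  lo <- x <= -37
  mid <- x > -37 & x <= 18
  hi <- x > 18 & x <= 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

#' Standardized generalized log-Burr distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the standardized generalized log-Burr distribution with shape
#' parameter `k`.  The density is
#' \deqn{f_0(z) = e^z (1 + e^z/k)^{-(k+1)}}{f0(z) = e^z (1 + e^z/k)^-(k+1)}
#' and the survivor (reliability) function is
#' \deqn{R_0(z) = (1 + e^z/k)^{-k}.}{R0(z) = (1 + e^z/k)^-k.}
#' `k = 1` gives the standard logistic distribution exactly and `k = Inf`
#' the standard extreme-value (Gumbel-minimum) distribution with density
#' \eqn{\exp(z - e^z)}.  Lifetimes arise through \eqn{t = \exp(\mu + \sigma z)}:
#' the `k = 1` member corresponds to log-logistic and `k = Inf` to Weibull
#' lifetime models.
#'
#' All computations use `log1p`/`expm1` forms and remain finite for
#' \eqn{|z|} up to several hundred, which censored likelihoods require.
#'
#' @param z vector of quantiles on the log-lifetime scale.
#' @param p vector of probabilities, strictly inside (0, 1).
#' @param n number of draws.
#' @param k shape parameter, a single positive number or `Inf`.
#' @param log,log.p logical; return log density / log probability.
#' @param lower.tail logical; if `FALSE`, the survivor function
#'   \eqn{R_0(z)} is returned instead of the distribution function.
#' @param seed optional integer seed for reproducible draws.
#' @return `dlogburr` the (log) density, `plogburr` the (log)
#'   distribution or survivor probability, `qlogburr` quantiles,
#'   `rlogburr` a numeric vector of `n` draws.
#' @examples
#' dlogburr(0, k = 1)            # 1/4, the logistic density at its mode
#' plogburr(0, k = 30, lower.tail = FALSE)
#' qlogburr(0.5, k = 1)          # 0, the logistic median
#' @export
dlogburr <- function(z, k, log = FALSE) {
  check_shape(k)
  lf <- if (is.infinite(k)) z - exp(z) else z - (k + 1) * log1pexp(z - log(k))
  if (log) lf else exp(lf)
}

#' @rdname dlogburr
#' @export
plogburr <- function(z, k, lower.tail = TRUE, log.p = FALSE) {
  check_shape(k)
  lsf <- if (is.infinite(k)) -exp(z) else -k * log1pexp(z - log(k))
  if (!lower.tail) {
    return(if (log.p) lsf else exp(lsf))
  }
  cdf <- -expm1(lsf)  # keeps precision when the survivor prob is near 1
  if (log.p) log(cdf) else cdf
}

#' @rdname dlogburr
#' @export
qlogburr <- function(p, k, lower.tail = TRUE) {
  check_shape(k)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!lower.tail) p <- 1 - p
  if (is.infinite(k)) {
    log(-log1p(-p))
  } else {
    # inverse of 1 - (1 + e^z/k)^(-k); expm1 keeps small-p precision
    log(k) + log(expm1(-log1p(-p) / k))
  }
}

#' @rdname dlogburr
#' @export
rlogburr <- function(n, k, seed = NULL) {
  check_shape(k)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  qlogburr(stats::runif(n), k)
}

#' Half-Cauchy density
#'
#' Density of the half-Cauchy distribution on \eqn{[0, \infty)} with scale
#' `scale`:
#' \deqn{p(x) = \frac{2}{\pi\,\alpha\,(1 + (x/\alpha)^2)}.}{p(x) = 2 / (pi * scale * (1 + (x/scale)^2)).}
#' With `scale = 25` (the default) the density is nearly flat over the
#' range of plausible lifetime scale parameters, making it the standard
#' weakly informative prior for a scale parameter: its mode is at 0, its
#' mean and variance do not exist, and unlike the inverse-gamma it is
#' well behaved near zero.
#'
#' @param x vector of non-negative values.
#' @param scale positive scale parameter.
#' @param log logical; return the log density.
#' @return numeric vector of (log) density values.
#' @examples
#' dhalfcauchy(0, scale = 25)    # the mode, 2 / (25 * pi)
#' @export
dhalfcauchy <- function(x, scale = 25, log = FALSE) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("half-Cauchy support is [0, Inf); negative `x` supplied",
         call. = FALSE)
  }
  ld <- log(2) - log(pi) - log(scale) - log1p((x / scale)^2)
  if (log) ld else exp(ld)
}
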