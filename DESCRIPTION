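Package: logburr
Title: Bayesian Inference for Generalized Log-Burr Lifetime Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bayesian fitting of right-censored lifetime data under the
    generalized log-Burr location-scale family, which contains the
    log-logistic (shape k = 1) and Weibull (k -> infinity) models as
    special cases.  Provides the censored log-likelihood with weakly
    informative priors (normal on regression coefficients, half-Cauchy on
    the scale), a deterministic Laplace approximation of the posterior,
    sampling importance resampling from the Gaussian approximation, and
    Random-Walk Metropolis simulation with thinning and a stationarity
    diagnostic.  Ships the classic locomotive-controls reliability data
    and a synthetic lifetime generator for grouped stress designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
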