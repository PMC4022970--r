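---
title: "Bayesian log-Burr lifetime models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian log-Burr lifetime models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logburr)
```

## The model

Lifetimes $t > 0$ are modelled on the log scale. With $y = \log t$, the
generalized log-Burr family assumes

$$y = \mu + \sigma z, \qquad \mu = X\beta,$$

where the standardized residual $z$ has density and survivor function

$$f_0(z) = e^z\left(1 + \frac{e^z}{k}\right)^{-(k+1)}, \qquad
  R_0(z) = \left(1 + \frac{e^z}{k}\right)^{-k},$$

with shape $k > 0$. The family nests the two classical lifetime models:
$k = 1$ is the standard logistic distribution for $y$ (log-logistic
lifetimes) and $k \to \infty$ the extreme-value distribution (Weibull
lifetimes), so a single likelihood lets the two be compared on equal
footing. On the lifetime scale the parameters map to
$\alpha = e^{\mu}$ (characteristic life) and shape $1/\sigma$.

`logburr_model()` accepts the aliases `"logistic"` ($k = 1$) and
`"weibull"`. The Weibull alias maps to the *finite* shape $k = 30$
rather than the limit: at $k = 30$ the family is already within
plotting accuracy of the extreme-value member while keeping one smooth
likelihood family for all configurations, and it is the conventional
finite-shape stand-in for Weibull fits in this family. The true limit
is available as `k = Inf`.

### Censored likelihood

Each observation carries an indicator $\delta_i$ (1 = failure observed,
0 = right-censored, the Type-I convention of a life test stopped at a
fixed time). With $z_i = (y_i - \mu_i)/\sigma$,

$$\ell(\beta, \log\sigma) =
  \sum_i \delta_i\left[\log f_0(z_i) - \log\sigma\right] +
  \sum_i (1 - \delta_i)\, \log R_0(z_i).$$

All distribution functions are evaluated in log space through
`log1p`/`expm1` forms (`dlogburr`, `plogburr`), so the likelihood stays
finite for standardized residuals out to $|z| \approx 700$; censored
records deep in a tail are exactly the situation in which naive
evaluation overflows.

### Priors and the monitored LP

Each coefficient gets an independent Normal$(0, 1000^2)$ prior and
$\sigma$ a half-Cauchy prior with scale 25 — both weakly informative:
nearly flat over any plausible value, yet proper, which keeps the
posterior integrable and gives the optimizer a defined target. The
parameter vector used everywhere is $(\beta, \log\sigma)$, flat order,
so the space is unconstrained.

One convention deserves emphasis: the half-Cauchy prior is evaluated at
$\sigma = \exp(\log\sigma)$ **without** a Jacobian term for the log
reparameterization. The log scale is treated as a device for
unconstrained optimization of the quantity
$\mathrm{LP} = \ell + \log p(\beta) + \log p(\sigma)$, not as a change
of the prior measure; `LP` then decomposes exactly as
$-\mathrm{Dev}/2 + \text{log prior}$, the identity the summary tables
and tests rely on. Adding the Jacobian would shift every monitored LP
by $\log\sigma \approx -0.9$ at the posterior and correspond to a
different (less standard, sigma-scale-dependent) prior.

## Laplace approximation

`fit_laplace()` maximizes LP deterministically and approximates the
posterior by a Gaussian at the mode $\hat\theta$ with covariance
$(-H)^{-1}$, $H$ the numeric Hessian of LP at $\hat\theta$.

Numerical choices:

* **Optimizers.** `"LBFGS"` (default) runs `stats::optim`'s L-BFGS-B
  and then polishes with full Newton steps until the gradient max-norm
  drops below `1e-5`; `"LM"` is a damped (Levenberg-style ridge) Newton
  ascent; `"NewtonRaphson"` is plain Newton with step halving. On this
  2–3-dimensional smooth posterior all three agree to `1e-4`; L-BFGS is
  the most forgiving of distant starting values, which is why it is the
  default. Default start: all zeros (coefficients 0, $\sigma = 1$).
* **Differencing.** Central differences with per-coordinate step
  $\max(10^{-4}, 10^{-4}|x_j|)$, validated on quadratic targets where
  the Hessian is exact.
* **Degeneracy.** If $-H$ is not positive definite its eigenvalues are
  floored at `1e-8` and the fit is flagged unconverged; `summary()`
  refuses unconverged fits. Nothing unusable is returned silently.
* **Intervals.** The analytic table reports
  $\mathrm{Mode} \pm 1.959964\,\mathrm{SD}$ as `LB`/`UB` — Gaussian
  2.5%/97.5% quantiles, the convention consistent with the asymptotic
  nature of the approximation.

## Sampling importance resampling

`sample_sir()` draws $M$ proposals from the fitted Gaussian, weights by
$\exp(\mathrm{LP} - \log q)$ (log-weights stabilized by subtracting
their maximum, so any unnormalized constant cancels), and resamples $S$
draws with replacement. The proposal is multivariate normal, not $t$:
for the near-Gaussian posteriors of this model class the lighter tails
cost little and the density is cheaper.

$M = 10S$ by default. For a 2–3-dimensional posterior whose Laplace
approximation is already accurate, a tenfold pool keeps the largest
normalized weight small (no degeneracy), while staying fast; both $S$
and $M$ are arguments. Monitors (`Deviance`, `LP`, `sigma`) are
recomputed at each retained draw and are exactly reconstructible from
the stored draws — a property the tests assert.

## Random-Walk Metropolis

`run_rwm()` is plain Metropolis with symmetric Gaussian increments:
accept $\theta'$ with probability $\min(1, \exp(\mathrm{LP}' -
\mathrm{LP}))$. Defaults follow standard practice for this posterior:
100000 iterations thinned by 100 (1000 retained draws), status logged
every 1000 iterations via `message()`.

* **Proposal covariance.** By default $(2.38^2/d)$ times the Laplace
  covariance — the classical optimal scaling for random-walk proposals
  on approximately Gaussian targets. On the intercept model this lands
  the acceptance rate near 0.36, inside the efficient range, and is
  testable (a 1-D standard normal target with proposal sd 2.4 gives the
  textbook 0.44).
* **Initial values.** The Laplace mode, so the chain starts in the
  stationary region and the burn-in diagnostic typically finds nothing
  to discard.
* **ESS / MCSE.** `effective_sample_size()` estimates
  $S\,\widehat{\mathrm{var}}(x)/\hat s_0$ with $\hat s_0$ the spectral
  density at frequency zero from an AIC-selected AR fit. On independent
  draws AIC selects order 0 and ESS $\approx S$; on an AR(1) chain it
  recovers the closed form $S(1-\rho)/(1+\rho)$. MCSE is
  $\mathrm{SD}/\sqrt{\mathrm{ESS}}$.
* **Stationarity split.** `stationarity_split()` scans burn-ins
  $0, S/10, \dots, S/2$ and keeps the smallest whose remaining chain
  passes a Geweke-style mean comparison of its two halves ($|z| < 2$ on
  every parameter). The variance in $z$ uses the spectral variance of
  the chain *tail*: estimating it from a half that still contains a
  transient lets the AR fit absorb the jump as near-unit-root variance
  and masks exactly the non-stationarity being tested — the
  constructed-transient test in the suite fails under that variant. If
  no candidate passes, the first half is dropped and the result is
  flagged with a warning rather than silently accepted.

## Synthetic data

`generate_lifetimes()` inverts the model: draw $z$ by inversion from
$f_0$, set $t = \exp(X\beta + \sigma z)$, censor at a fixed time if
requested. Inversion keeps the output a deterministic function of one
seed. Two canonical designs:

* an intercept-only life test with Type-I censoring, structurally the
  locomotive-controls experiment;
* `fluid_like_spec()`, a seven-group constant-stress design (76 units
  at 26–38 kV, uncensored) emulating the classic insulating-fluid
  breakdown experiment. The stress covariate enters as log-voltage —
  the inverse-power-law convention for dielectric breakdown — and the
  per-group allocation (3, 5, 11, 15, 19, 15, 8) is a synthetic
  emulation, not the historical measurements; the defaults
  $\beta = (64, -17.5)$, $\sigma = 0.9$ give lifetimes of realistic
  magnitude for that design.

What the generator does *not* emulate: covariate-dependent or random
censoring, overdispersion/frailty, measurement error in the stress
variable, or model misspecification. Passing recovery tests therefore
demonstrates the estimation machinery is consistent under the assumed
model, not robustness to violations of it.

The test suite exercises recovery at sizes chosen to make bias visible
against Monte-Carlo noise while keeping the suite quick: 20 replicates
of $n = 2000$ intercept-only data with ~30% censoring (coefficient
recovered within $\pm 0.05$, $\log\sigma$ within $\pm 0.1$), and one
$n = 760$ grouped regression recovered within 3 posterior SDs.
Simulation summaries use $S = 1000$ SIR draws and 100000-iteration
chains thinned to 1000 — the same sizes as the reference analyses of
the locomotive data.

## Worked intercept analysis

```{r laplace}
d <- locomotive_data()
fit <- fit_laplace(d, logburr_model("logistic"))
summary(fit)
```

```{r sir}
summary(sample_sir(fit, S = 1000, seed = 1))
```

```{r rwm}
chain <- run_rwm(fit, iterations = 20000, thinning = 20,
                 status_interval = Inf, seed = 1)
acceptance_rate(chain)
summary(stationarity_split(chain)$stationary)
```

## Known limitations

* Right censoring only; left/interval censoring, time-varying
  covariates and frailty terms are out of scope.
* The shape $k$ is configuration, not a parameter to be estimated;
  model choice between logistic and Weibull configurations is by
  comparing fits.
* Single-chain MCMC: no Gelman–Rubin diagnostic, no adaptive samplers.
  The stationarity split is a within-chain diagnostic and cannot detect
  a chain stuck in one mode of a multimodal posterior (not a concern
  for this log-concave-like family in practice).
* The Laplace covariance is asymptotic; for very small or heavily
  censored samples the SIR/RWM quantiles are the ones to report.
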