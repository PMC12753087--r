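---
title: "Inference for the inverted exponentiated Rayleigh model under progressive hybrid Type-I censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference for the inverted exponentiated Rayleigh model under progressive hybrid Type-I censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ierphc)
```

## The model

The inverted exponentiated Rayleigh (IER) distribution is a two-parameter
lifetime model on $x > 0$ with distribution function

$$F(x;\theta,\lambda) = 1 - \left[1 - e^{-\lambda x^{-2}}\right]^{\theta},
\qquad \theta, \lambda > 0,$$

shape $\theta$ (the exponent) and scale $\lambda$ (inside the exponential).
It arises as the law of the reciprocal of an exponentiated Rayleigh variate.
Its hazard rate is non-monotone (upside-down bathtub) for a wide range of
parameter values, which suits event times such as symptom-relief or
remission durations where risk first rises and then declines.  `dier`,
`pier`, `qier`, `rier`, `ier_reliability`, `ier_hazard` and `ier_cumhaz`
evaluate the model functions; the quantile function is closed-form,
$x = \sqrt{-\lambda / \log\!\big(1 - (1-u)^{1/\theta}\big)}$, and random
generation is inverse-transform.

Throughout the package $\theta$ **always denotes the exponent** and
$\lambda$ the scale.  When comparing with published tables of this model it
is worth checking which role each printed symbol actually plays (plugging
the printed values into $R(x)$ is a quick diagnostic), because the two
labels are easy to exchange.

## The censoring design

A progressive hybrid Type-I censored (PHT-ICS) life test places $n$ units on
test with a removal plan $R_1,\dots,R_m$ ($\sum R_i = n - m$) and a time
limit $T$.  At the $i$-th failure, $R_i$ surviving units are withdrawn.  The
test stops at $\min(X_{m:m:n}, T)$:

* **Case I** — the $m$-th failure comes first: $r = m$ failures observed,
  termination at $C = X_{m:m:n}$, no terminal removal;
* **Case II** — the clock fires first: only $r = d < m$ failures observed,
  $C = T$, and the remaining $R^*_T = n - d - \sum_{i\le d} R_i$ units are
  withdrawn at $T$.

`censoring_plan`, `censoring_scheme` (the three benchmark one-point removal
patterns), `rprogressive`, `phtics_truncate` and `rphtics` implement design,
generation and truncation.  Every generated sample satisfies the accounting
identity $n = r + \sum_{i \le r} R_i + R^*_T$, which the test suite checks on
hundreds of draws.

Generation uses the uniform-spacings representation of progressive Type-II
order statistics: with $\tau_i$ iid uniform,
$v_i = \tau_i^{1/(i + \sum_{j=m-i+1}^m R_j)}$ and
$U_i = 1 - v_m v_{m-1}\cdots v_{m-i+1}$ are progressively censored uniform
order statistics, mapped through the IER quantile function.  The exponent
index runs over the full planned scheme of size $m$ — the generator always
produces the complete progressive Type-II sample and the hybrid time limit
is applied afterwards as a separate truncation step.  A replicate in which
no failure precedes $T$ ($d = 0$) carries no likelihood information; the
generator raises an error and leaves the retry policy to the caller (the
Monte-Carlo engine redraws with the next derived seed and counts the event).

## Likelihood inference

With observed failures $x_1 < \dots < x_r$ and writing
$w(x) = 1 - e^{-\lambda x^{-2}}$, the log-likelihood is

$$\ell(\theta,\lambda) = \sum_{i=1}^r \log f(x_i)
  + \theta \sum_{i=1}^r R_i \log w(x_i) + \theta R^*_T \log w(C),$$

each withdrawn unit contributing a survival factor at its withdrawal time.
For fixed $\lambda$ the $\theta$-score has the closed-form root
$\hat\theta(\lambda) = r / Q_\lambda$,
$Q_\lambda = -\sum (1+R_i)\log w(x_i) - R^*_T \log w(C)$, so the fit reduces
to a one-dimensional search.  `fit_ier` first runs BFGS in
$(\log\theta, \log\lambda)$ with the analytic gradient — positivity without
constraints, and robust when heavy censoring leaves the shape direction
flat — then polishes the result to machine precision with a bracketed root
solve of the profiled scale score.  The convergence flag requires the
log-scale gradient max-norm to fall below $10^{-6}$; in practice the
polished fits sit at $10^{-9}$ or better.  Default starting values need no
user input: $\lambda_0 = \mathrm{median}(x)^2 \log 2$ (the exact median
relation when $\theta = 1$) and $\theta_0 = \hat\theta(\lambda_0)$.

Standard errors come from inverting the analytic observed information
(`ier_observed_info`; the test suite verifies it against central
finite differences at $10^{-4}$ relative tolerance).  Reliability and hazard
estimates at a mission time follow by invariance, with delta-method
variances using the closed-form gradients of $R$ and $H$ in
$(\theta,\lambda)$.  Two interval flavors are reported: the plain Wald
interval (ACI-NA), whose lower bound may be negative and is deliberately not
truncated, and the log-scale interval (ACI-NL),
$\hat\xi \exp(\pm z_{\gamma/2}\,\mathrm{se}/\hat\xi)$, which respects
positivity.

## Maximum product of spacings

The MPS criterion replaces density contributions by log CDF increments
between consecutive ordered failures (boundary conventions $F(x_0)=0$,
$F(x_{r+1})=1$) while keeping the same survival powers for removed units:

$$s(\theta,\lambda) = \sum_{i=1}^{r+1}
  \log\left[w(x_{i-1})^\theta - w(x_i)^\theta\right]
  + \theta \sum_{i=1}^r R_i \log w(x_i) + \theta R^*_T \log w(C).$$

MPS is attractive under small samples and heavy censoring, where the
likelihood can be badly behaved.  Two numerical points matter:

* **Ties.**  Real measurements are recorded on a rounded grid, so tied
  observations occur (the bundled relief-time data contain several) and a
  tied pair makes its spacing exactly zero.  Following the standard remedy,
  a zero spacing is replaced by the density $f(x_i;\theta,\lambda)$, applied
  per tied pair, and the analytic gradient/Hessian use the corresponding
  log-density derivatives.  The objective therefore stays finite on every
  bundled sample.
* **Stability.**  Spacings are formed from log-survival values via
  `expm1`, so they remain accurate when $w^\theta$ underflows.

`fit_ier(method = "mps")` shares the optimizer, starting values and
convergence policy with the likelihood route, and `ier_mps_info` supplies
the observed-information analogue for MPS-based Wald intervals.  The
derivative code is verified against finite differences on tie-free samples;
estimates agree with the MLE to well under 2% at $n = 5000$ complete
observations.

## Bayesian estimation

Independent gamma priors (rate parameterization) are placed on both
parameters: $\theta \sim \mathrm{Ga}(a,b)$, $\lambda \sim \mathrm{Ga}(c,d)$.
The $\theta$ full conditional is then exactly
$\mathrm{Ga}(a + r,\; b + Q_\lambda)$ — a conjugacy that the sampler module
exploits twice: `ier_bayes(sampler = "gibbs")` draws $\theta$ exactly, and
the default Metropolis-within-Gibbs chain (`sampler = "mh"`, Gaussian
random-walk proposals for both parameters) is required by the test suite to
reproduce the Gibbs marginal within Monte-Carlo error.  This dual-route
check is the module's primary correctness gate, and an exact 2-D quadrature
of the posterior kernel was used during development as a further oracle.

Sampler policy: chains initialize at the MLEs; proposal standard deviations
default to the asymptotic standard errors of the MLEs (a multiplicative
`proposal_scale` is exposed, default 1, since no tuning rule is prescribed);
non-positive proposals are rejected outright because the target density
vanishes there.  Defaults are 12,000 iterations with 2,000 burn-in for
simulation-sized problems; the single-dataset report uses 50,000 with
10,000 burn-in.  The near-noninformative prior sets all four
hyperparameters to 0.001.

Point estimates: posterior mean under squared-error loss, and under LINEX
loss $-a^{-1}\log E[e^{-a\xi}]$ (log-sum-exp guarded; $a \to 0$ recovers the
mean, and Jensen's inequality forces LINEX$(a>0) \le$ mean $\le$
LINEX$(a<0)$, which is asserted on every chain).  Intervals: equal-tailed
quantile intervals and HPD intervals computed as the shortest contiguous
window of sorted draws containing the nominal fraction — the implementation
is tested to match an exhaustive search over all windows exactly.
`posterior_summary` reports mean, kernel-density mode (Gaussian kernel, 512
grid points), quartiles (type-7 interpolation, as for all quantiles in the
package), standard deviation and moment skewness.

## The Monte-Carlo engine and its study conditions

`simulation_design` fixes the evaluation conditions; its defaults are the
benchmark conditions used throughout the package's own validation: truth
$(\theta,\lambda) = (0.4, 0.8)$, thresholds $T \in \{1.5, 2.5\}$,
$(n,m) \in \{(40,20), (40,32), (80,40), (80,64)\}$ (50% and 80% failure
budgets), the three one-point removal schemes, mission time $x_0 = 0.5$,
informative priors $(2,5,4,5)$ and $(4,10,8,10)$ — whose means equal the
true parameters — LINEX shapes $\mp 2$, and 1000 replicates.
`run_monte_carlo` reports, per cell and estimator, the average point
estimate, RMSE and mean relative absolute bias for $\theta$, $\lambda$,
$R(x_0)$ and $H(x_0)$, plus average length and coverage of ACI-NA and HPD
intervals, each with a Monte-Carlo standard error so that runs at reduced
replicate counts can be compared on a principled scale.  The package's test
suite exercises single cells at 60–500 replicates, which keeps the default
check under a minute per cell while leaving averages within a few
Monte-Carlo standard errors of their 1000-replicate values; the full grid is
a deliberate opt-in computation.

Per-replicate seeds derive deterministically from the design seed, so any
cell or replicate can be reproduced in isolation.  The engine never mutates
bundled fixtures.

What the generator emulates — and what it does not: samples are exactly
continuous draws from the assumed IER model under the planned censoring
design.  Passing tests therefore demonstrate correctness of the estimators
*under the model*, not robustness to rounding (real relief times are
recorded to one decimal and contain ties), to model misspecification, or to
informative withdrawal mechanisms; none of those are emulated.

## Goodness of fit and the single-dataset workflow

`ks_gof` computes the one-sample Kolmogorov-Smirnov statistic by direct
enumeration of the ECDF jumps and its p-value from the asymptotic
Kolmogorov series with the supplied parameters treated as known.  Plugging
in fitted values therefore yields the conventional—but optimistic—fit check
(no correction of the Lilliefors type is applied); this matches how such
checks are usually reported for this model family, and the caveat should be
kept in mind when reading the p-value.  `empirical_reliability` and
`loglik_grid` export the step function and the likelihood surface that the
standard diagnostic plots are built from.  `real_data_report` chains the
whole workflow — both classical fits, the posterior sample, all interval
flavors and posterior summaries — and is byte-stable given a seed.

The bundled data (`arthritis_relief`, 50 relief times recorded in tens of
hours, and `arthritis_phtics("S1")`–`"S4"`, four censored subsamples with
$m = 25$ and differing removal patterns and thresholds) provide a realistic
small-sample workload: ties, heavy censoring (S1 observes only 20 of 50
units), and both stopping cases.

## Numerical choices, in one place

* $\log(1 - e^{-y})$ via `expm1`/`log1p` branches everywhere; all model
  functions stay finite for $\lambda x^{-2}$ up to several hundred.
* Optimization in log-parameters with analytic gradients; Nelder-Mead
  fallback; MLE polished by a bracketed univariate root solve of the
  profiled score.
* Parameter validation raises an error immediately rather than propagating
  `NaN`: optimizers work on the log scale, so invalid values indicate bugs,
  not data.
* A failure exactly at the threshold (a probability-zero event) counts as
  observed; the middle removal index of the second benchmark scheme is
  $\lceil m/2 \rceil$.
* HPD window width is $\lfloor \mathrm{level} \cdot M \rfloor$ draws;
  quantiles are type-7 throughout.

## Known limitations

* Intervals are first-order asymptotic or sample-quantile constructions; no
  bootstrap calibration is provided.
* Wald intervals for strongly skewed estimands under heavy censoring can
  undercover; the log-scale and HPD flavors are the recommended defaults in
  that regime.
* The Metropolis chain mixes slowly for the scale parameter on heavily
  censored small samples (batch-means standard errors are the honest
  uncertainty measure; expect effective sample sizes well below the raw
  draw count).
* Only fixed (pre-planned) removal vectors are supported — no binomial or
  adaptive removal models.
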