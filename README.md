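# ierphc

Inference for the **inverted exponentiated Rayleigh (IER)** lifetime
distribution when data arise from **progressive hybrid Type-I censoring**
(PHT-ICS).

## The problem

Reliability and clinical follow-up studies rarely observe every failure.
Under a progressive hybrid Type-I design, `n` units go on test with a
removal plan `R_1, ..., R_m` and a time limit `T`: at the i-th failure,
`R_i` surviving units are withdrawn, and the test ends at the m-th failure
or at `T`, whichever comes first (Case I / Case II).  The IER model

    F(x; θ, λ) = 1 − [1 − exp(−λ x⁻²)]^θ ,   x > 0,  θ, λ > 0

with shape (exponent) `θ` and scale `λ` has an upside-down-bathtub hazard

    H(x; θ, λ) = 2 θ λ x⁻³ exp(−λ x⁻²) / (1 − exp(−λ x⁻²))

and suits event times like symptom-relief durations.  The package provides,
for samples censored this way:

* **Model functions and simulation** — `dier`/`pier`/`qier`/`rier`,
  `ier_reliability`, `ier_hazard`, `ier_cumhaz`; censoring plans, the
  uniform-spacings progressive Type-II generator and hybrid truncation
  (`censoring_plan`, `rphtics`), with plain-text sample I/O.
* **Maximum likelihood** — `fit_ier`: profile-reduced, machine-precision
  fits; analytic score and observed information; invariance estimates of
  `R(x)` and `H(x)` with delta-method standard errors; Wald (ACI-NA) and
  log-scale (ACI-NL) intervals.
* **Maximum product of spacings** — `fit_ier(method = "mps")`: the spacings
  criterion with survival powers for removed units, analytic derivatives,
  and a density substitution for tied observations.
* **Bayesian estimation** — `ier_bayes`: Metropolis–Hastings within Gibbs
  under independent gamma priors (the θ conditional is exactly
  Gamma(a + r, b + Q_λ); an exact-Gibbs sampler is built in as a
  cross-check), squared-error and LINEX point estimates (`bayes_point`),
  equal-tailed and HPD intervals, posterior summaries.
* **Study harness** — `simulation_design`/`run_monte_carlo` (APE, RMSE,
  MRAB, ACL, CP with Monte-Carlo standard errors), `ks_gof`,
  `empirical_reliability`, `loglik_grid`, `real_data_report`, and the
  bundled arthritis relief-time data (`arthritis_relief`,
  `arthritis_phtics("S1")`–`"S4"`).

A thin command-line front end lives at `inst/cli/ierphc.R`
(`simulate`, `fit`, `bayes`, `gof`, `report`).

## Worked example

Fit the heavily censored first arthritis subsample (20 failures observed
out of 50 units, unit removals at each failure, time limit 7.4):

```r
library(ierphc)
fit_ier(arthritis_phtics("S1"), x0 = 5)
#> IER MLE fit (converged): theta = 1.3098 (SE 0.5375), lambda = 46.5674 (SE 11.4510)
#> objective = -58.0206
#> R(5) = 0.8017 (SE 0.0482), H(5) = 0.1794 (SE 0.0410)
#>   quantity flavor     lower    upper   length
#> 1    theta ACI-NA  0.256259  2.36336  2.10711
#> 2   lambda ACI-NA 24.123848 69.01094 44.88709
#> ...
```

The fitted exponent 1.31 and scale 46.57 imply an estimated 80.2% chance
that relief takes more than 50 hours (`x = 5` on the data's tens-of-hours
scale), with a hazard of 0.179 there.  The complete 50-observation sample
passes a Kolmogorov–Smirnov fit check against the fitted IER model:

```r
f <- fit_ier(arthritis_relief())
ks_gof(arthritis_relief(), f$theta, f$lambda)
#> K-S = 0.1269, p = 0.3962
```

Posterior inference under near-noninformative gamma priors:

```r
draws <- ier_bayes(arthritis_phtics("S1"), n_iter = 12000, burnin = 2000,
                   x0 = 5, seed = 7)
draws
#> IER posterior draws (mh sampler): 10000 kept of 12000 (burn-in 2000)
#> acceptance: theta 0.49, lambda 0.52
#> posterior means: theta 1.2946, lambda 45.0156, R(5) 0.7988, H(5) 0.1737
hpd_interval(draws$H)
#> 95% HPD for H(5): (0.0999, 0.2482)
```

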