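# rtscale

Survey platforms record, as a byproduct of administration, how long each
respondent spends on each question screen. These response-time (RT)
*paradata* carry signal about cognitive functioning: how fast a person
answers on average, how strongly they calibrate their speed to the demands
of each item, and how erratically their timing fluctuates beyond that.
`rtscale` implements the full analysis chain for extracting these
person-level RT components from long-format survey RT records and linking
them to cognitive test scores, both cross-sectionally and prospectively
across time lags. A synthetic panel generator with known ground truth makes
every stage testable without access to any restricted panel data.

## The models

Let `RT_ij` be the natural log of the seconds person *j* spent on item *i*
(items are filtered for eligibility, trimmed per item at the 99th
percentile, and log-transformed with a 1-second floor).

**Location-scale model.** A two-level model with random effects on both the
person mean ("location") and the log of the person residual variance
("scale"):

    RT_ij = alpha_j + r_ij,          r_ij ~ N(0, sigma_j^2)
    alpha_j = gamma00 + u0j
    log(sigma_j^2) = omega + u1j,    (u0j, u1j) ~ MVN(0, tau)

**Expanded location-scale model.** Survey items differ in *time intensity*
(TI) — the latent expected log time an item requires, the RT analogue of
item difficulty, estimated from a crossed person-by-item random-effects
model and centered at a 10-second reference. The expanded model adds a
person-specific slope on centered TI:

    RT_ij = alpha_j + beta_j * TIc_i + r_ij
    alpha_j = gamma00 + u0j
    beta_j  = gamma10 + u1j
    log(sigma_j^2) = omega + u2j,    (u0j, u1j, u2j) ~ MVN(0, tau)

`alpha_j` is the person's predicted log RT for a 10-second item (*mean
RT*), `beta_j` their *systematic RT adjustment* to item demands, and
`omega + u2j` their *residual RT variability*. Estimation is by a
Metropolis-within-Gibbs sampler with diffuse priors; person components are
posterior (empirical-Bayes) means. An adaptive Gauss–Hermite quadrature
oracle provides an independent route to the marginal likelihood for
validation.

Downstream, the three components enter standardized multiple regressions
of cognitive test scores (optionally with demographic covariates and an
age-40 moderation), and a "lag-as-moderator" analysis: the models are
refitted per survey, components are averaged within half-year lag bins
before the cognitive test, and per-bin standardized coefficients with
cluster-robust (person-clustered) standard errors yield the maximum lag at
which associations remain stable.

## Worked example

```r
library(rtscale)

cfg <- panel_config(n_persons = 300, n_surveys = 6, items_per_survey = 25,
                    tau = diag(c(0.16, 0.04, 0.25)), seed = 101)
panel <- generate_panel(cfg)
clean <- preprocess_rt(panel$rt_records, panel$items)
ti    <- estimate_time_intensities(clean, method = "reml")
fit   <- fit_expanded_location_scale(clean, ti,
                                     ls_spec(iterations = 4000, seed = 7))
fit
#> expanded_location_scale fit: 300 persons, 44550 records
#>   gamma00 = 2.302, gamma10 = 1.002, omega = -1.735
#>   tau:
#>         [,1]    [,2]    [,3]
#> [1,]  0.1433 -0.0026 -0.0215
#> [2,] -0.0026  0.0372  0.0062
#> [3,] -0.0215  0.0062  0.2021
#>   max PSR = 1.003 (converged)

comps <- extract_person_components(fit)
regress_components(panel$scores, comps)
#> Regression of number_series on RT components (n = 300)
#>           term   beta    se     t        p
#>    (Intercept)  0.000 0.052  0.00 1.00e+00
#>        mean_rt -0.270 0.053 -5.12 5.47e-07
#>  rt_adjustment  0.345 0.052  6.58 2.12e-10
#>  log_resid_var -0.072 0.053 -1.37 1.73e-01
#> F(3, 296) = 23.82, R^2 = 0.194, p = 7.72e-14
```

The fit recovers the generating parameters (`gamma00 = 2.33`,
`gamma10 = 1.0`, `omega = -1.66`, `tau` diagonal `.16/.04/.25`) within
sampling error. The component regression shows the expected sign pattern;
at n = 300 the coefficients on the empirical-Bayes components are
attenuated relative to the generating values `(-0.28, 0.50, -0.15)`
because the estimated components carry measurement noise — on the true
latents at n = 5000 the coefficients and the generating R² of .26 are
recovered to within Monte-Carlo error (this is one of the checks in
`scripts/acceptance.R`). `run_pipeline()` drives all stages — including
the per-survey fits, lag binning and lag-as-moderator regression — from a
single seeded configuration and writes CSV/JSON artifacts plus a manifest.

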