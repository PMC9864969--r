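---
title: "Inferring cognitive abilities from survey response-time paradata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cognitive abilities from survey response-time paradata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

Web panels time every question screen. Those per-item response times (RTs)
are *paradata* — collected incidentally, at population scale, with no
additional respondent burden. `rtscale` treats them as a measurement
instrument for three person-level quantities:

* **mean RT** — how long a person takes on a reference item;
* **systematic RT adjustment** — how strongly the person calibrates their
  speed to how demanding each item is;
* **residual RT variability** — how much their timing fluctuates beyond
  mean and calibration, a candidate marker of attentional lapses and
  processing noise.

The package implements the full chain — preprocessing, item
time-intensity estimation, Bayesian location-scale modeling, component
extraction, cross-sectional association, and time-lagged stability
analysis — together with a synthetic panel generator that reproduces the
assumed generative model with known truth, so that every stage is
validated by parameter recovery rather than by fiat.

## Preprocessing

Working on the natural-log scale throughout (`log_rt = ln(seconds)`):

* **Item eligibility** (`filter_items()`): only items shown individually
  on a page (grid/matrix screens share one timestamp), closed-ended, and
  completed by at least 75% of the survey's respondents. The completion
  denominator is the number of distinct persons with any record in that
  survey; the rule boundary is inclusive (exactly 75% is kept).
* **Person eligibility** (`filter_min_surveys()`): at least 5 distinct
  surveys per person by default.
* **Trimming** (`trim_rts()`): per item, records strictly above the
  empirical 99th percentile are removed. The quantile is the inverse-CDF
  (order-statistic) definition, not an interpolated one: an interpolated
  threshold falls strictly below the retained maximum, so re-trimming
  would keep shaving records, whereas an attained order statistic makes
  the trim exactly idempotent. Removal, not winsorizing, because the
  targeted records (respondents stepping away from the screen) carry no
  usable timing signal. Note that with fewer than 100 respondents on an
  item the 99th-percentile threshold is the item maximum and nothing is
  trimmed; the procedure is designed for the large-panel regime
  (thousands of respondents per item).
* **Log transform** (`log_transform()`): sub-second RTs are floored at
  1 s before taking logs (so the minimum possible log RT is 0.00), which
  avoids a long negative tail driven by accidental double-clicks;
  dropping them instead is available as an option.

## Item time intensities

The *time intensity* (TI) of an item is the latent expected log time it
requires — the RT analogue of item difficulty. `estimate_time_intensities()`
fits the crossed random-effects model

`log RT_ij = mu + p_j + q_i + e_ij`

and returns `ti_log = mu + EB(q_i)` per item, where EB is the posterior
mean. Two estimators are provided: a fully conjugate Gibbs sampler
(default; diffuse inverse-gamma(0.001, 0.001) priors on the three
variances, flat prior on `mu`, deterministic given a seed) and a REML path
via `lme4` used for speed and as an independent cross-check — the two
agree to well within estimation error on common inputs, and the tiny-data
empirical-Bayes estimates are tested against a direct generalized
least-squares solve of the mixed-model equations.

TIs are centered at a 10-second reference (`ti_centered = ti_log -
ln(10)`), chosen because typical survey items average close to 10 seconds;
the downstream model intercept then reads as the predicted log RT for a
10-second item. TIs enter downstream models as fixed, known covariates
(two-stage procedure). This deliberately ignores TI estimation
uncertainty; with hundreds-to-thousands of observations per item the TI
standard errors are negligible relative to the person-level posterior
spread, and the package flags items with fewer than 10 observations rather
than propagating their uncertainty.

## The location-scale models

The basic model gives each person a random mean and a random log residual
variance:

```
RT_ij = alpha_j + r_ij,            r_ij ~ N(0, sigma_j^2)
alpha_j = gamma00 + u0j
log(sigma_j^2) = omega + u1j,      (u0j, u1j) ~ MVN(0, tau)
```

The expanded model splits within-person variability into calibration and
noise by adding a random slope on centered TI:

```
RT_ij = alpha_j + beta_j TIc_i + r_ij
beta_j = gamma10 + u1j,   log(sigma_j^2) = omega + u2j,
(u0j, u1j, u2j) ~ MVN(0, tau)
```

The log link on the residual variance keeps `sigma_j^2` positive and makes
the scale effects approximately normal.

### Sampler

`fit_location_scale()` / `fit_expanded_location_scale()` use a
Metropolis-within-Gibbs scheme that operates entirely on per-person
sufficient statistics (n, sums, cross-products), so iteration cost scales
with persons, not records:

1. location effects `(u0j[, u1j])` — exact conjugate normal draws given
   the scale effects (conditioning on `u2j` through the MVN prior);
2. scale effects `u2j` — per-person random-walk Metropolis with
   per-person step sizes adapted toward 0.44 acceptance during burn-in
   and frozen afterwards (so the post-burn-in chain is a valid fixed
   kernel);
3. fixed effects `(gamma00[, gamma10])` — conjugate normal;
4. `omega` — adaptive random-walk Metropolis;
5. translation moves that shift mass between each fixed effect and the
   mean of the corresponding random effects. The likelihood is invariant
   under these shifts, so acceptance depends only on the priors; they
   dramatically improve mixing of the fixed effects against the
   random-effect means;
6. `tau` — conjugate inverse-Wishart.

Priors are `N(0, 1e6)` on fixed effects and inverse-Wishart (identity
scale, df = dim + 1) on `tau` — a concrete rendering of "software default
diffuse priors". Defaults: 2 chains, 4000 iterations, half burn-in.
Convergence is summarized by the potential scale reduction factor across
chains per parameter, flagged at 1.05. Chains are initialized from
data-derived values with chain-specific offsets (overdispersed starts) and
every result is deterministic given `spec$seed`.

The sampler was validated two independent ways: posterior means agree with
an identically specified JAGS fit to about three decimals on small data,
and with maximum marginal likelihood computed by the package's own
adaptive Gauss–Hermite quadrature (`marginal_loglik_quadrature()`,
`mml_estimate()`) to within 0.05 on 15–20-person toys. The quadrature
oracle recenters and rescales a tensor-product Gauss–Hermite grid at each
person's conditional posterior mode (log-sum-exp accumulation for
stability) and collapses to the closed form when `tau = 0`.

### Known information floors

With homogeneous data (`tau = 0`), posterior means of the `tau` diagonal
cannot reach zero: the inverse-Wishart scale contributes `~1/J`, and each
person's scale effect is informed only at rate `n_j/2`, so the
scale-variance posterior floors at roughly `(1 + J E[u^2]) / J` with
`E[u^2] ~ 1/(1/tau + n_j/2)`. At 100–150 items per person this floor sits
near 0.014; it drops below 0.01 only at several hundred items per person —
which is the realistic regime (panel respondents average ~550 analyzed
items). Degenerate-limit tests therefore use ~500 items per person.

### Person components

`extract_person_components()` returns per-person posterior means and SDs
of `alpha_j`, `beta_j` and `omega + u_scale,j`. Posterior means are used
(not modes) because they are the Bayes-optimal point estimates under
squared error and the shrinkage they embody is exactly what the
down-stream attenuation diagnostics expect. Persons with very few records
are retained: their components are prior-dominated and their posterior SDs
say so.

## Synthetic panel generator

`generate_panel()` draws persons' `(u0, u1, u2)` from MVN(0, tau), item
TIs from a truncated normal (mean 2.29, SD 0.5, bounds 1.14–4.04 log
seconds), and log RTs from the expanded model with `gamma00 = 2.33`,
`gamma10 = 1`, `omega = -1.66`; the `omega` default makes the implied
marginal SD of pooled log RT about 0.79, matching the marginal summaries
of large web panels. The survey calendar staggers panel entry uniformly
over two years with surveys every 60 days; the cognitive test follows
1–60 days after the last survey, so everyone has at least five completed
surveys before testing whenever the panel has five surveys.

Cognitive scores sit on a T-score metric (mean 50, SD 10):
`score = 50 + 10 (sum_k beta_cog[k] z_k + e)` with `z_k` the
population-standardized latents and the noise variance set so the latent
signal explains exactly `r2_cog` of the score variance. One subtlety: with
uncorrelated latents the default coefficient pattern `(-0.28, 0.50,
-0.15)` would force R² = 0.35, not the default `r2_cog = 0.26`. The
default `tau` therefore carries modest latent correlations
(cor(u0, u1) = 0.25, cor(u1, u2) = 0.14 — the plausible direction given
that marginal component-score correlations are typically much weaker than
the partial coefficients), which makes `beta' R beta = 0.26` and the two
defaults mutually consistent: the generated scores then have exactly the
stated standardized coefficients *and* the stated R². For other
configurations the realized standardized coefficients scale by
`sqrt(r2_cog / beta' R beta)`, documented in `?panel_config`.

Contamination replaces a configurable fraction of records with the clean
seconds multiplied by Uniform(10, 50) — a respondent walking away — and
marks them, so trim recall is measurable. Age moderation multiplies the
u0-score coefficient for the 40+ group. Demographics are categorical draws
with marginals matching a large US internet panel; they act only as
regression covariates.

What the generator does *not* emulate: item content effects, device and
time-of-day effects, attrition beyond staggered entry, satisficing
response styles, and autocorrelated ("coherent") RT dynamics. Passing
recovery tests therefore demonstrates that the estimation machinery is
correct under the model's assumptions, not that real panels satisfy them.

## Association and lagged analyses

`regress_components()` z-scores the outcome and the components over the
listwise-complete analysis sample, so component coefficients are
standardized betas; categorical covariates enter as unstandardized
indicators, continuous ones (age) z-scored. `moderated_regression()` fits
one model with group-by-component interactions; within-group betas come
from the cell-means parameterization of the same fit and the interaction
t is the group-difference test. No multiple-testing correction is applied;
the number of tests is visible in the outputs.

The lagged pipeline refits the model per survey
(`fit_per_survey_components()`, reusing the global TIs and per-survey
seeds), averages components within person and half-year lag bin
(`assign_lag_bins()`; bin k covers `(0.5(k-1), 0.5k]` years, bin 1 closed
at 0, lags above 6.5 years dropped), and stacks one row per person-bin
with the score repeated (`lag_moderator_regression()`). Because the
outcome repeats within persons, clustering on persons is mandatory: the
package owns the sandwich algebra (CR0 meat from per-cluster score sums,
`G/(G-1)` small-sample factor, exposed in config) and tests it against
both a brute-force computation and `sandwich::vcovCL`. Per-bin confidence
intervals use `t(G-1)` quantiles; the component-by-lag interaction and the
component main effect (mean slope across bins) are cluster-robust Wald F
tests with denominator df `G-1`. The design matrix is built as explicit
cell-means columns, so a single-bin analysis degenerates exactly to the
cross-sectional regression. `max_stable_lag()` reports the longest run of
bins, starting at the first, whose CIs all exclude zero (a missing bin
breaks the run); `classify_effect_size()` applies the .10/.30/.50
conventions.

Components are z-scored over the stacked rows (so betas are comparable
across bins), the outcome over distinct persons. The empirical size of the
interaction test was checked by simulation (200 replicates of a
lag-constant generator at 150 clusters x 4 bins) and is within binomial
bounds of the nominal 5%.

## Problem sizes and reproducibility

The validation suite uses 300 persons x 150 items for parameter recovery
and empirical-Bayes quality (fixed effects recovered within ±0.05,
variance components within 15%, PSR < 1.05; component-truth correlations
≥ .95/.85/.70), 15–20-person toys for the quadrature oracle, ~500 items
per person for degenerate limits, n = 5000 true-latent samples for
association recovery, and 20000 respondents per item for trim recall —
sizes at which each check is informative while the whole suite runs in a
few minutes on one core. `run_pipeline()` fans a single run seed out to
per-stage seeds via `stage_seed()`, writes all artifacts with a checksum
manifest, and identical configurations reproduce byte-identical numbers.

## Limitations

* TI uncertainty is not propagated (two-stage design, matching the
  procedure the models are built around).
* The scale-effect posterior needs many items per person; with short
  panels the residual-variability component is heavily shrunk and its
  variance estimate has a prior-driven floor (see above).
* Cluster-robust inference assumes many clusters; bins with fewer than
  two persons are excluded rather than patched.
* The trim is designed for items answered by hundreds-plus of
  respondents; below 100 respondents per item it removes nothing.
* Reverse-scored Stop-and-Go latencies are a negation, defensible up to
  any strictly decreasing transform; correlations are invariant to the
  choice up to sign.
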