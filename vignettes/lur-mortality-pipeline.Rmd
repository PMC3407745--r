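---
title: "Land use regression exposure models and cohort mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression exposure models and cohort mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lursurv)
```

## What the package models

Long-term exposure to traffic-related air pollution is usually assigned to
epidemiological cohorts through land use regression (LUR): measured NO2
concentrations at a few dozen monitoring sites are regressed on geographic
and traffic covariates, and the fitted surface predicts exposure at every
residential address. A recurring methodological question is whether a LUR
model built from one monitoring campaign can stand in for exposure in a
different period — whether spatial contrasts in a city are stable over a
decade or more, and whether mortality associations are robust to which
campaign the exposure model came from.

`lursurv` implements that whole chain as reusable, tested components:

1. a synthetic radial city with a known latent NO2 surface, monitoring
   campaigns, co-located dual-sampler pairs, and a cohort with known
   exposure–mortality structure (`generate_city()`, `simulate_true_surface()`,
   `simulate_campaign()`, `simulate_colocated_pairs()`, `simulate_cohort()`);
2. GIS predictor construction at arbitrary points
   (`assemble_predictor_table()`);
3. between-sampler calibration and Bland–Altman agreement
   (`fit_calibration()`, `bland_altman()`);
4. the LUR fitter itself — sign-constrained manual backward stepwise
   regression on log concentrations (`lur_fit()`);
5. validation: leave-one-out cross-validation, variance inflation factors,
   Cook's distances, Moran's I of residuals (`loocv()`, `vif()`,
   `cooks_distance()`, `morans_i()`), and cross-period transportability
   (`cross_period_predict()`, `build_stability_report()`);
6. cohort exposure assignment, categorisation and description
   (`assign_exposure()`, `categorize_exposure()`, `stratified_summary()`,
   `cuzick_trend()`);
7. a self-contained Cox proportional-hazards fitter (`cox_fit()`,
   `hr_for_increment()`, `trend_across_categories()`);
8. `run_pipeline()`, which executes all stages in order and writes every
   intermediate artifact.

Because the real monitoring measurements and cohort it emulates are not
public, the synthetic city is first-class: every statistical claim the
package makes is verified against ground truth that the generator knows.

## The LUR model

Site annual means are the arithmetic mean of the per-period values, with
sites lacking any required period dropped (`site_period_mean()`). The model
is ordinary least squares on the log scale,

$$\log \mathrm{NO_2}(s) = \beta_0 + \sum_k \beta_k x_k(s) + \varepsilon(s),$$

over the candidate predictors: the raw planar coordinates, distance to the
city centre, altitude, census-block size, residents, inverse population
density (m² per person), green-area adjacency, metres of high-traffic road
(>10,000 vehicles/day) within a 150 m buffer, traffic density in that
buffer (vehicles·m/m²), and distance to the nearest high-traffic road.
Only one buffer radius is used (150 m, configurable).

Selection is *manual backward stepwise with a sign constraint*, mirroring
standard LUR practice:

* each predictor except the coordinates has an expected direction
  (`expected_signs()`); a retained coefficient contradicting it removes the
  predictor (worst violator first, by p-value);
* otherwise the predictor with the largest p-value above `p_remove = 0.20`
  is dropped;
* the two coordinates are paired: while one holds p ≤ 0.20, the other may
  not be removed, so a model never contains just one coordinate selected on
  significance.

Ties in p-values are broken by removing the predictor that appears later in
the canonical schema ordering (`lur_predictors()`); the data cannot break
such ties, so the rule only needs to be deterministic. The sign rule is
applied iteratively at every step by default (`sign_rule = "iterative"`);
`"prescreen"` instead drops wrong-signed predictors once, based on their
univariate slopes, before elimination begins. We default to the iterative
rule because a predictor's sign can flip as collinear companions leave the
model, and re-checking is the only way to guarantee the final model's signs.

Predictions back-transform by plain exponentiation. A Duan-type smearing
correction was considered and deliberately omitted from the default path:
the residual log-variances involved here (≈ 0.01) bias predictions by under
1%, and the downstream uses (correlations, hazard ratios per increment) are
insensitive to a constant multiplicative factor. `loocv()` refits
*coefficients only*, with the selected predictor set held fixed — the
standard LUR reading of leave-one-out validation; a full re-selection mode
(`reselect = TRUE`) exists for sensitivity analyses. Cross-validated R²,
adjusted R² and RMSE are reported on the concentration scale (μg/m³), while
the in-sample RMSE of the fit is on the log scale; both conventions are
common and the package keeps them clearly separated.

### Numerical edge cases

With noiseless data the OLS residual variance underflows and t-statistics
become meaningless; `lur_fit()` detects a numerically perfect fit
(RSS ≤ 1e-16 · TSS) and then classifies coefficients by their standardized
magnitude: negligible terms get p = 1 (and are eliminated), real terms
p = 0. The same guard sets all Cook's distances to zero for an exact fit.
Constant predictor columns are removed before elimination starts, with a
note in the fitting trace. Rank deficiency at any point is an error, not a
silent drop.

## Diagnostics

* **VIF**: `1/(1 - R²_k)` from regressing predictor *k* on the others;
  perfect collinearity reports `Inf` rather than erroring.
* **Cook's distance**: classical formula via the hat matrix; verified in
  the tests against literal leave-one-out refitting.
* **Moran's I** of model residuals with inverse-distance, row-standardized
  weights by default (binary k-nearest and distance-band schemes are
  options). The null expectation is −1/(n−1). The default test is a
  two-sided permutation test, p = (extreme + 1)/(n_perm + 1) with 999
  permutations and an explicit seed; a normal-approximation test under the
  randomization assumption is also implemented. Permutation is the default
  because n ≈ 70 sites is small enough that the normal approximation's
  accuracy depends on the weight structure.

## The synthetic city

The generator emulates the broad structure of a large radial European city:

* a 30 km square with the centre in the middle; population density decays
  exponentially from the centre (e-folding 9 km) with strong mean-one
  lognormal block-to-block heterogeneity (sd 0.7 on the log scale) — real
  census blocks vary widely around any radial trend, and without that
  heterogeneity the block covariates would be near-deterministic functions
  of distance and the regression design would be close to singular;
* 8 radial arterials (5 segments each) and 2 ring roads whose vehicle
  counts fall from ≈ 45,000/day near the centre to just above the
  4,000/day representation floor at the edge, so both high-traffic
  (>10,000) and moderate roads exist;
* a smooth altitude field rising towards the north-east corner (20–120 m)
  with sinusoidal relief, deliberately *not* collinear with the raw
  coordinates;
* a latent log-linear surface with active coefficients on both coordinates,
  distance to centre, altitude, buffer traffic density and distance to the
  nearest high-traffic road (`surface_params()`); the intercept (4.40) was
  set so that cohort exposures average ≈ 45 μg/m³. The active effects were
  sized so that each contributes roughly 0.05–0.13 sd on the log scale at
  the monitoring sites — large enough that an 80-site campaign has
  adequate power to identify every active predictor, which is the premise
  of the package's parameter-recovery checks;
* spatially correlated Gaussian noise on the log scale (sd 0.1,
  exponential covariance with 1,000 m range), simulated by Cholesky
  factorisation on a 31×31 grid and bilinear interpolation. The field
  exists so that residual spatial autocorrelation is *controllable*: the
  Moran diagnostics need both correlated and independent regimes;
* a between-campaign drift of −0.06 on the log scale plus −8e-4 per unit
  traffic density, reproducing a small overall decline that is somewhat
  stronger at traffic sites while preserving rank order;
* samplers with affine response distortion; the default distorted sampler
  uses gain 1/0.68 and offset −13.53/0.68, so that regressing the reference
  sampler on the distorted one recovers the familiar correction line
  `reference = 0.68 · distorted + 13.53`;
* a cohort whose exponential survival times have log-hazard linear in NO2
  (default log(1.06) per 10 μg/m³) and in the categorical covariates, with
  administrative censoring at 5.2 years and a baseline hazard solved
  numerically for a 6.5% event fraction. The 5-level area socioeconomic
  category comes from a latent score `0.8 · scale(NO2) + N(0,1)` cut at
  quintiles, giving the positive exposure–status association seen in
  cities whose affluent population concentrates centrally; all other
  covariates are drawn independently of location, since only the
  socioeconomic index has documented spatial structure in the setting
  emulated.

What the generator does **not** emulate: real street-network geometry,
meteorology and seasonal chemistry, residential mobility, measurement
drift within a campaign, or the heavy-tailed block-size distribution of a
real census. Consequently, passing tests demonstrate the *statistical
machinery* — selection, validation, calibration, survival estimation — on
data whose generating process is known; they do not certify predictive
accuracy on any real city.

## The Cox fitter

`cox_fit()` maximizes the log partial likelihood by Newton–Raphson with
step-halving, using time-on-study as the time scale and age as an adjuster
(the convention when age is one covariate among several). Efron's tie
correction is the default, Breslow optional. Convergence requires a score
below 1e-8 *and* a small final step, or a relative log-likelihood change
below 1e-10; the step condition matters because under a monotone
likelihood the score vanishes while the estimate still drifts — that case
(|coef| > 20) is reported as a monotone-likelihood error rather than a
fit. Covariance is the inverse observed information; confidence intervals
are Wald on the log scale. Exposure enters linearly per 10 μg/m³, as
quintile indicators, or as the four fixed classes (≤35, 35–45, 45–50,
>50 μg/m³, left-open/right-closed); reference categories are the lowest
exposure group and each covariate's most frequent level. The test suite
checks the fitter against closed-form roots, a grid-search oracle and an
independent survival implementation.

`hr_for_increment()` rescales the linear coefficient to any increment,
including the exposure IQR; `trend_across_categories()` replaces category
dummies with an ordinal 0,1,2,… score and reports the Wald p for its
coefficient — the usual reading of a "p for trend" across ordered exposure
groups.

Quintile boundaries use linear-interpolation (type 7) quantiles with ties
to the lower group; the descriptive tables use the same quantile type. The
gender contrast uses Welch's unequal-variance t-test; the trend across
ordered age/socioeconomic groups uses Cuzick's rank test with midranks and
a tie-corrected variance.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed and is a pure
function of (inputs, seed); `run_pipeline()` derives per-stage seeds from
the global seed by stable hashing of stage names, so inserting a stage
does not shift the streams of earlier ones. The shipped verification runs
use 67–81 monitoring sites per campaign (emulating the two campaigns'
designs), cohorts of 20,000 subjects for survival checks, 100 replicates
for parameter-recovery and interval-coverage rates, 1,000 null datasets
for the Moran level check, and 50 replicates for the cross-period
stability ordering; these sizes give Monte-Carlo error comfortably inside
the asserted bands while keeping a full run in minutes on a single core.

## Known limitations

* Geometry is planar; no geodesy. Scenes are already in projected metres.
* GeoJSON I/O covers the schema this package writes (LineString roads,
  Polygon blocks, scalar properties), not arbitrary GeoJSON.
* The stepwise fitter inherits the classical caveats of p-value-driven
  selection: post-selection inference is not corrected, and with a 0.20
  retention threshold some null predictors are expected in the final
  model (about one in ten per null candidate). The package treats the
  fitted model as a prediction tool, as LUR practice does.
* `simulate_cohort()` generates exponential baselines only; the Cox fitter
  itself is, of course, agnostic to the baseline hazard.
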