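# lursurv

Land use regression (LUR) exposure models for NO₂ and their association
with mortality in a cohort — implemented end to end and verifiable on a
synthetic city with known ground truth.

## The problem

Cohort studies of long-term air pollution and mortality need an exposure
estimate at every residential address, but concentrations are measured at
only a few dozen monitoring sites, often in a single campaign years before
or after follow-up. Land use regression bridges the gap: regress measured
NO₂ on geographic and traffic covariates, then predict at the addresses.
Whether a model built from one campaign can stand in for another period —
whether a city's spatial contrasts are stable — is an empirical question
this package makes fully testable, because it ships a synthetic radial
city in which the true latent surface, the between-campaign drift, the
sampler distortions and the cohort's exposure–mortality structure are all
known.

For monitoring sites *s* the model is ordinary least squares on the log
scale,

    log NO₂(s) = β₀ + Σₖ βₖ xₖ(s) + ε(s),

over coordinates, distance to centre, altitude, census-block covariates
and three traffic variables (metres of high-traffic road and traffic
density within a 150 m buffer, distance to the nearest high-traffic road).
Selection is manual backward stepwise elimination (p > 0.20) with a sign
constraint — predictors whose coefficient contradicts the expected
direction are excluded — and a pairing rule that keeps both geographic
coordinates whenever one is selected. Exposure at the addresses feeds Cox
proportional-hazards models of natural mortality (quintiles, four fixed
classes, linear per 10 μg/m³ and per interquartile range), fitted by the
package's own Newton–Raphson partial-likelihood maximizer with Efron tie
handling.

## Worked example

```r
library(lursurv)
res <- run_pipeline(pipeline_config(cohort_n = 5000), seed = 11)
print(res)
#> Synthetic-city exposure and mortality pipeline
#>   LUR 1: 65 sites, adj R2 = 0.919 | LUR 2: 76 sites, adj R2 = 0.909
#>   r measured (shared sites) = 0.993, r assigned (addresses) = 0.995
#>   per-10 HR: model 1 = 1.044 (0.950-1.148), model 2 = 1.041 (0.942-1.151)
```

The run simulates a radial city, two three-week monitoring campaigns
(the first with a distorted passive sampler, calibrated back through 27
co-located pairs), fits and validates one LUR model per campaign, assigns
both exposures to a cohort of 5,000, and fits the Cox models. The printed
summary says: both campaigns' models explain ≈ 91% of log-concentration
variance; the two campaigns' *measurements* correlate 0.993 at shared
sites while the two models' *assigned exposures* correlate 0.995 at the
addresses (model smoothing removes measurement noise, so the assigned
correlation is the higher one); and the estimated hazard ratios per
10 μg/m³ bracket the generating value of 1.06 — at this cohort size the
confidence intervals are wide, which is why the verification runs use
20,000 subjects.

The fitting log of each model replays every elimination:

```r
summary(res$lur1)
#> Elimination steps:
#>  step       predictor         reason   p_value
#>     1      block_size       constant        NA
#>     2 block_residents sign_violation 0.7847799
#>     3 hi_road_len_150 sign_violation 0.5310353
#>     4  green_adjacent        p_value 0.5009345
#>     5 inv_pop_density        p_value 0.3532794
```

Individual stages are plain functions: `generate_city()`,
`simulate_campaign()`, `fit_calibration()`, `site_period_mean()`,
`lur_fit()`, `loocv()`, `vif()`, `cooks_distance()`, `morans_i()`,
`cross_period_predict()`, `assign_exposure()`, `cox_fit()`,
`hr_for_increment()`, `build_stability_report()`. See the vignette in
`vignettes/lur-mortality-pipeline.Rmd` for the model, the generator's
design and its limitations.

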