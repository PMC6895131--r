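# fireocc

Bayesian hierarchical occupancy models for estimating how wildfire burn
severity and **pyrodiversity** — the spatial heterogeneity of severity —
affect species occurrence and community diversity, from acoustic
detection/non-detection surveys with imperfect detection. The package grew
out of analyses of multi-year bat monitoring across burned conifer-forest
landscapes, where a 17-species community is surveyed over ~200 site-year
survey periods of 1–17 nights each, and burn severity is measured as
percent basal-area mortality (0–100%) around each survey point.

## The model

For one species, each site-year survey period `i` has a latent occurrence
state `z_i ~ Bernoulli(psi_i)` and nightly observations
`y_ij ~ Bernoulli(p_ij * z_i)`, with

```
logit(p_ij)  = a0 + a1 day + a2 day^2 + a3 canopy + a4 noise + a5 temperature + a6 mic
logit(psi_i) = b0 + b_site[i] + b_area[i] + b1 elevation + b2 water_distance
               + b3 sev + b4 sev^2 + b5 pyrodiversity
```

All continuous covariates are standardized; `sev` is the buffer mean of
percent basal-area mortality at one of four candidate radii (50/100/250/
500 m) and `pyrodiversity` is the residual of buffer severity SD regressed
on severity and its square. The latent `z` is marginalized analytically in
the likelihood; sampling is by a self-contained adaptive Metropolis sampler
(compiled, non-centered random intercepts), 3 chains × 2000 iterations with
split-R-hat monitoring. Per-species fits at the four radii are compared by
LOOIC computed with Pareto-smoothed importance sampling, and the lowest
LOOIC wins. Community richness is `sum_s psi_s` propagated over posterior
draws; beta diversity is the pairwise Jaccard dissimilarity of
detection-corrected occurrence matrices drawn from the conditional
distribution of `z` given the data.

A full account of the model, priors, conventions and limitations is in the
methods vignette (`vignettes/occupancy-fire-methods.Rmd`).

## Worked example

Simulate a survey campaign under known parameters and recover them:

```r
library(fireocc)

land   <- generate_landscape(grid_size = 160, cell_m = 50,
                             spatial_corr_length_m = 100, seed = 1)
design <- sample_design(land, n_sites = 122, n_years = 4, seed = 2)
#> <survey_design> 122 sites, 209 survey periods, 1266 survey nights

covs <- build_covariates(land, design, radii = c(100, 250))
md   <- occu_model_data(design, covs, radius = 250)

tp  <- true_params(alpha = c(0, 0.25, -0.25, -0.25, -0.5, 0.25, 0.25),
                   beta  = c(0, 0.5, -0.25, 1.0, -0.5, 0.75))
sim <- simulate_detections(md, tp, seed = 3)
fit <- fit_occupancy(md, sim$y, seed = 4)
summary(fit)
#>             param  mean    sd     q5   q50     q95 rhat
#> 1          alpha0 -0.11 0.165 -0.398 -0.11  0.1618    1
#> ...
#> 11          beta3  1.19 0.336  0.666  1.18  1.7470    1
#> 12          beta4 -0.67 0.254 -1.089 -0.66 -0.2413    1
#> 13          beta5  0.96 0.230  0.591  0.95  1.3756    1
```

The severity coefficients (`beta3`–`beta5`, truth 1.0/−0.5/0.75) are
recovered within their 90% credible intervals; `alpha0` near 0 means the
species is detected on about half the nights at occupied sites. Model
comparison across radii uses the stored pointwise log-likelihood draws:

```r
psis_loo(fit$loglik)
#> <psis_loo> elpd_loo = -473.52 (SE 34.51), LOOIC = 947.04; max Pareto k = 0.11
```

Community-level summaries take a named list of per-species fits:
`richness_curve()` for posterior richness over severity × pyrodiversity,
and `beta_summary()` for Jaccard dissimilarity versus severity distance
with severity-class means.

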