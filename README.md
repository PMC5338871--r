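# reefspawn

Tools for predicting **when and where reef fish spawn** from
fishery-independent survey collections and seafloor terrain, for fisheries
scientists and spatial managers working with trap/longline reef-fish surveys
(e.g. shelf-edge snapper–grouper assemblages).

Reproductive histology classifies each mature female as in *spawning
condition* (oocyte maturation or post-ovulatory follicles, i.e. captured
within ~48 h of spawning) or not. The package models the probability that an
examined mature female is in spawning condition as a logit-linked binomial
mixed model,

```
logit P(spawning_i) = x_i' beta + u_year(i),   u_year ~ N(0, sigma^2)
```

where the fixed effects are survey and habitat covariates — month, bottom
temperature, latitude and depth bins, a signed lunar-luminosity covariate
(waxing positive, waning negative), gear, habitat, selected interactions —
and terrain statistics (mean/max bathymetric position index, slope, aspect,
curvature in buffers around each gear set), with a year random intercept.
Model building follows a two-stage forward-stepwise AIC search (survey
covariates first, then the large terrain suite) guarded by a pairwise
correlation screen (|r| > 0.60 blocked), 10-fold cross-validated ROC
evaluation with a TPR+TNR-maximizing threshold and an AUC utility grade, and
a 500-replicate permutation test for spurious terrain covariates. Selected
models are projected onto a prediction grid at peak spawning settings,
standardized to Z-scores, and checked against independent validation points
(support = Z > 0). Spawning-site fidelity is summarized by single-linkage
multi-year spawning areas sized by minimum convex polygon.

Because survey databases of this kind are not public, the package ships a
synthetic-data module (`sim_config()`, `generate_bathymetry()`,
`generate_survey()`) that generates a shelf-edge bathymetry surface and
survey collections from a fully known spawning model, so that every stage of
the pipeline is testable for parameter recovery and calibration.

## Worked example

```r
library(reefspawn)

# a synthetic survey whose true spawning model is known
cfg    <- sim_config(seed = 1, n_years = 10, n_sets_per_year = 42)
bathy  <- generate_bathymetry(cfg)
ter    <- terrain_stack(bathy)              # slope, aspect, curvature, BPI
survey <- generate_survey(cfg, bathy, ter)

# terrain statistics in 381.8 m buffers around each gear set
xy  <- lonlat_to_xy(survey$records$lon, survey$records$lat, cfg$ref)
pts <- unique(data.frame(id = survey$records$set_id, x = xy$x, y = xy$y))
buf <- summarize_buffer(ter, pts, radius = 381.8)

design <- build_design(survey$records,
                       terms   = c("month", "temperature", "lunar", "mean_bpi_broad"),
                       buffers = buf)
fit <- spawn_glmm(design, nAGQ = 1)
print(fit)
#> <spawn_fit> glmer_laplace, n = 2677
#>   terms: month, temperature, lunar, mean_bpi_broad
#>   logLik = -1204.524, AIC = 2437.05, year SD = 0.4436

cv <- crossvalidate(design, fit$terms, k = 10, seed = 1)
print(cv)
#> <cv_report> pooled AUC 85.30% (good), FPR 28.03%, FNR 14.49%
#>   fold-mean AUC 85.41%, pooled threshold 0.3044, seed 1
```

The fit recovers the generative model: the fitted temperature coefficient
(per degree C on the logit scale) and the year random-intercept SD sit close
to the simulation truth (0.25 and 0.5 here), and the cross-validated AUC of
~85% grades the model "good" on the conventional scale (excellent 90–100,
good 80–89, fair 70–79, poor < 70). `predict_map()` then turns the fit into
a peak-spawning probability surface with delta-method standard errors and
Z-scores; `external_validation()` reports the fraction of independent points
lying above the domain-mean probability; `cluster_multiyear()` and
`mcp_area()` delineate and size multi-year spawning areas.

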