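---
title: "Modeling reef fish spawning timing and locations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reef fish spawning timing and locations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reefspawn)
```

This vignette is the package's account of its science: the model, the
choices made where the methodology was genuinely open, the numerical
conventions, and what the synthetic-data tests do and do not demonstrate
about real survey data.

## The response and the model

The unit of analysis is a single histologically examined mature female.
Histology classifies her as in *spawning condition* — oocyte maturation
(nucleus migration through hydration) or post-ovulatory follicles, evidence
of spawning within roughly 48 hours — or as a mature non-spawning female.
Sites with no females of the species are deliberately absent: including
them would confound probability of occurrence with probability of spawning.

The response is modeled at the fish level as a Bernoulli outcome in a
logit-linked mixed model with a single year random intercept:

$$\operatorname{logit} P(y_i = 1) = \mathbf{x}_i'\boldsymbol\beta + u_{year(i)},
\qquad u \sim N(0, \sigma^2).$$

Year is random because year-to-year processes (sampling changes,
recruitment pulses, selective pressure) shift the spawning/non-spawning
ratio without being of direct interest. All other effects are fixed.
Covariates within a gear set are shared by every fish in it. A set-level
reading of the response ("any spawner in the set") is also defensible; we
model the fish level because the probability statement is about detecting
*a female* in spawning condition, and set-level aggregation is recoverable
from the records.

The model is fit by maximizing the marginal likelihood, integrating the year
intercept out by adaptive Gauss–Hermite quadrature (21 nodes by default,
through `lme4::glmer`). The Laplace approximation (`nAGQ = 1`) is used
beyond 40 year levels; `nAGQ = 0` (fixed effects profiled out by penalized
IRLS) is the screening mode used inside large stepwise and permutation
loops, where thousands of fits are compared by AIC and the ≤ 0.02 AIC-unit
discrepancy against the Laplace fit is immaterial. Final reported fits
always use `nAGQ` ≥ 1. With a single year level, or when the variance
estimate hits the zero boundary, the fit coincides with ordinary logistic
regression. Complete separation — likely in small species-level data sets
with factor covariates — is flagged on the fit; an optional Jeffreys-prior
(Firth) penalized solution is available for the fixed-effects path, off by
default so that the default estimator is the plain MLE.

The Wald interval reported for the random-intercept SD is constructed on the
log scale, $\hat\sigma \exp(\pm 1.96\, \widehat{se}/\hat\sigma)$, with the
standard error taken from the numerical hessian of the marginal deviance.
The log scale respects positivity and the right skew of SD estimates with
~10 year levels; in the package's own calibration simulations it attains
close to nominal 95% coverage where the symmetric interval is visibly
anticonservative.

## Covariates

**Terrain.** All derivatives are computed on elevation (= −depth).
The bathymetric position index (BPI) of a cell is its elevation minus the
mean elevation over an annulus, with membership by center-to-center
Euclidean distance in cell units, inner radius 1 and outer radii 18
(broad scale) and 9 (fine scale) for 90 m cells; the exact annulus mask of
desktop GIS tools is undocumented, so the half-open rule
`inner < d ≤ outer` is declared here. BPI is kept floating point — integer
rounding (offered as a switch) is a desktop-tool artifact that quantizes
fine-resolution grids. Slope and aspect use Horn's 3×3 weighted finite
differences; curvature is the Zevenbergen–Thorne 3×3 quadratic-fit general
curvature, −(z_xx + z_yy) in 1/100 m, positive convex. Whether profile,
plan, or general curvature was historically used is unstated in the
literature this follows; general curvature is the default and the estimator
is isolated so it can be switched. Buffers around gear sets use a 381.8 m
radius for 90 m layers (the hypotenuse of a 3×3 block of 90 m cells) and
127 m for fine multibeam-scale layers; the mean and maximum of each layer
over cells whose centers fall inside the circle are recorded. Mean aspect is
a circular (unit-vector) mean, since arithmetic averages of angles are
meaningless, and flat cells (undefined aspect) are excluded.

**Lunar covariate.** The signed lunar luminosity is
$\pm(1-\cos\theta)/2$ with phase angle $\theta$ proportional to days since
the previous new moon over a 29.53059-day synodic month — positive waxing,
negative waning, so the covariate sweeps 0 → +1 → −1 → 0 over a month. An
optional mode snaps the value to the nearest quarter. "Rounded to the
nearest quarter moon" could alternatively mean snapping dates to
quarter-phase events; value-rounding is the default here and the other
reading is deliberately not asserted. The new-moon reference table shipped
with the package is computed from the mean lunation (a synthetic ephemeris,
labeled as such): true new moons deviate by up to ~0.6 d, a ≤ 7° phase
error, negligible for a luminosity covariate.

**Binning.** Month is a factor. Other continuous predictors are binned by
type-7 quantiles (default quartiles) and treated as factors, avoiding
imposed linear dose–response shapes; fixed schemes (1° latitude bins, 20 m
depth bins from 10–70 m) are available. Bins are left-closed/right-open on
their interior edges, the outer bins unbounded; duplicate quantile edges
collapse with a logged warning. Temperature stays continuous. Empty factor
levels are removed; bin edges and level sets are stored with the design and
the fit so predictions re-encode new data identically. Records with missing
or non-positive temperature are dropped only when a temperature term is in
the model. Interactions (latitude×depth, latitude×month,
latitude×temperature) are factor crosses of the binned margins.

## Model selection and validation

Stage 1 screens the survey covariates by forward-stepwise AIC: at each step
the candidate with the largest AIC decrease enters, candidates whose
pairwise association with an included term exceeds 0.60 are blocked
(absolute Pearson correlation on underlying continuous values where both
exist, Cramér's V otherwise; exactly 0.60 is allowed — the inequality is
strict), and interactions wait for their margins unless explicitly
overridden. Stage 2 offers the terrain suite to the stage-1 winner, and a
terrain term is retained only if it lowers AIC **and** does not degrade
predictive utility. The latter is operationalized — no numeric rule exists
in the methodology this implements — as: the candidate model's
cross-validated pooled AUC may not fall more than 0.5 percentage points
below the stage-1 model's. Exact AIC ties break by candidate order.

Cross-validation uses 10 class-stratified folds (stratification prevents
single-class training folds; the seed is recorded in the report). Per fold,
the classification threshold maximizes TPR + TNR on the *training* ROC,
taking the lowest optimal observed-score candidate on ties, and the held-out
rows are classified at that threshold. AUC is computed by the rank-sum
(Mann–Whitney) formulation with midranks for ties, reported pooled over the
concatenated test predictions; per-fold means are also reported since either
convention is defensible. FPR and FNR come from the accumulated confusion
counts. Utility grades: excellent (AUC ≥ 90%), good (≥ 80), fair (≥ 70),
poor below, boundaries upward.

The spuriousness check for the terrain term permutes every terrain candidate
independently (a permutation preserves each column's marginal distribution
exactly), refits the final non-terrain model plus each permuted candidate
singly, takes the best AIC reduction per replicate, and records that
candidate's percent deviance explained. The spurious probability is the
fraction of 500 replicates (the shipped default) whose best permuted
candidate explains more deviance than the true term.

Percent deviance explained is computed on the marginal scale: deviance is −2
times the marginal log-likelihood, the null deviance is that of the
intercept-only fixed-effects fit, and each step of the nested sequence —
including the addition of the year random intercept itself — contributes
$100(\mathrm{dev}_{i-1}-\mathrm{dev}_i)/\mathrm{dev}_0$. Contributions
telescope to the total exactly. Whether such decompositions should be
marginal or conditional is genuinely open; marginal matches the likelihood
being maximized.

## Prediction maps and validation

Prediction grids aggregate the 90 m terrain layers to 270 m cells by 3×3
block means (circular means for aspect) and block maxima, with block-mean
depth; cells on land or deeper than 200 m are nodata. Predictions are
population-level (year intercept at 0) — multi-year maps imply year-free
predictions — with month, temperature and lunar phase fixed at their peak
values, by default the level or value maximizing the fitted linear
predictor, overridable to a published species-specific peak. Standard errors
are delta-method: the SE of the linear predictor mapped through
$p(1-p)$. Probabilities (not linear predictors) are standardized to
Z-scores over the whole non-nodata domain with the population SD.
Latitudes beyond the fitted bin range fall into the nearest outer bin, and
factor levels unseen in training map to the reference level with a logged
warning (strict mode raises instead) — the prediction domain is
deliberately wider than the sampled domain. An independent validation point
supports the model when the Z-score under it is strictly positive, i.e. its
predicted probability exceeds the domain mean.

## Spawning areas

A spawning event is a gear set that retrieved at least one
spawning-condition female; multispecies events have two or more species.
Multi-year spawning areas are single-linkage clusters of a species' events
at a 1.1 km cutoff — the repeat-observation radius used for site fidelity —
that span at least two sampling years. No quantitative clustering rule
exists in the methodology this implements ("difficult to quantitatively
determine the edges"); single-linkage at a configurable cutoff is declared
as this package's rule, not asserted as the original one. The percent of
years with spawning uses as denominator the years in which any histological
sample of the species fell within the cutoff of a member event. Areas are
sized as minimum convex polygons in a Lambert azimuthal equal-area
projection centered on the point set (hulls in raw geographic coordinates
are refused); fewer than three non-collinear points give 0 km², and
rounding to whole km² is left to report formatting.

## The synthetic survey

The generator emulates a shelf-edge survey: a depth ramp (10–200 m) with
one or more Gaussian ridge features and smooth correlated noise; gear sets
placed uniformly over depth-eligible cells (no sampling-bias model is
published, so none is default); sampling months weighted to May–September
with light March/April and October effort; bottom temperature from a
seasonal cycle minus a depth lapse plus noise; the lunar covariate from the
date; and per-female spawning flags drawn Bernoulli at a known logit that
combines intercept, temperature, latitude, depth, lunar, a June-peaked
cosine month effect, a broad-scale BPI effect, and year intercepts
N(0, 0.5) by default. The per-set female count is uniform on 1–12 — a
documented guess, as no count distribution is published. True
probabilities and year effects are written to a sidecar file so the
analysis path consumes exactly the public CSV schema.

What passing tests show: the estimators recover the generative parameters
at survey scale (n ≈ 4,000, 10 years), the selection machinery finds real
effects and resists pure noise at calibrated rates, and the geometry and
terrain operators agree with brute-force oracles. What they cannot show:
robustness to preferential (hardbottom-targeted) set placement, gear
selectivity, spatially structured residual confounding, or
terrain-covariate error in real bathymetry — none of which the generator
emulates.

## Numerical conventions and problem sizes

Quadrature uses 21 nodes by default; the likelihood oracle test checks the
marginal log-likelihood against 10,001-node trapezoid integration to 1e−4.
The correlation screen compares with a 1e−9 epsilon so an association of
exactly 0.60 stays on the allowed side of the strict inequality. Stepwise
ties break by candidate order; ROC threshold ties break to the lowest
optimal threshold. Zero-variance prediction grids yield all-zero Z-scores
with a warning rather than an error. The test suite runs its
calibration simulations at n ≈ 2,000–4,000 females, 10 years, and 100
replicates (permutation tests at 100 replicates instead of the shipped
500); `scripts/acceptance.R` runs one full pipeline at 10 years × 42
sets/year (~2,700 females) with 8 terrain candidates. These sizes are the
package's declared study conditions for its own calibration claims.

## Known limitations

Single random intercept only (no crossed or nested random effects, no
smoothers — the linear-predictor approach is deliberate, favoring stable
extrapolation over in-sample flexibility). The correlation screen's
Cramér's V between factors is a heuristic counterpart to "correlation >
60%". Equirectangular local projection is used for buffers and clustering;
at survey scale (tens of km) the distortion is far below one cell. The
synthetic ephemeris is a mean-lunation approximation. Esri ASCII is the
only raster interchange format read or written.
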