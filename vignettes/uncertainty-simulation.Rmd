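---
title: "Simulating data-quality uncertainty in species distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating data-quality uncertainty in species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmuncert)
```

## The procedure

A species distribution model run in this package is a chain:

1. six bioclimatic predictors are derived from 36 monthly climate
   layers (12 months each of minimum temperature, maximum temperature,
   precipitation);
2. a presence–background suitability model is fitted to occurrence
   records against a background sample of the study region;
3. the logistic suitability surface is thresholded into a binary
   presence/absence map;
4. the fitted model is projected onto future climates built by the
   delta (anomaly) method, one per GCM × emissions scenario.

Uncertainty propagation wraps this chain in a Monte Carlo loop. A
*source specification* names which inputs are perturbed; each replicate
draws a fresh perturbation from that source's error model, reruns steps
1–4 (predictors are recomputed only when the climate itself is
perturbed), and stores the binary maps. The per-cell mean of the stack
is the presence-probability map: the proportion of model runs
predicting presence. All randomness descends from a single master seed
through a documented integer hash (`derive_seed()`), so any individual
replicate — or any single noise field inside a replicate — can be
regenerated in isolation, and a rerun of the same configuration is
bit-identical.

Failed replicates (for example, a perturbation leaving fewer than five
usable presences) are logged and excluded from the denominator; more
than 20% failures aborts the run, on the view that a probability map
silently built from a biased subset of replicates is worse than an
error.

## The suitability model

The default backend is a ridge-penalized logistic regression of
presence (1) against background (0) on standardized linear and
quadratic transforms of the six bioclim predictors. This is the
smallest member of the MaxEnt family of presence–background models:
linear + quadratic features correspond to fitting means and variances
of the predictor distribution under the exponential model, and the
ridge penalty plays the role of MaxEnt's regularization. The backend
sits behind a narrow fit/predict interface precisely because the
contribution of this package is the perturbation machinery around the
model, not the model itself; a full MaxEnt implementation could be
swapped in without touching the Monte Carlo layer.

Two conventions matter for reproducibility:

- **Class weighting.** Presences and background each receive total
  weight 1/2, regardless of counts. Standardization of the features
  uses the same weights. Both the fit and the feature scaling are then
  invariant to duplicating records within a class, and the intercept
  absorbs the (arbitrary) background sample size.
- **Threshold rule.** The rule that separates presence from absence is
  configurable; the default maximizes sensitivity + specificity over
  the observed suitability values, resolving ties to the lowest
  candidate. The percentile rule uses the nearest-rank convention
  (rank `ceiling(p/100 * n)` of the ascending presence suitabilities).
  The threshold is recomputed per replicate on the training
  (current-climate) data and reused for that replicate's future
  projections — the internally consistent reading when the question is
  how a current-climate model transfers forward. Models are likewise
  fitted once per replicate on current climate and projected onto
  every scenario, rather than refitted per scenario.

Default settings: background 10,000 points (capped at the available
unmasked cells), ridge weight 0.01 (small but non-zero, enough to keep
strongly correlated climate predictors from exchanging large opposing
coefficients), threshold rule max sensitivity + specificity.

## The error models

**Locational error** displaces each record by an isotropic bivariate
Gaussian offset. "An average of 10 km of noise" is read as the *mean
Euclidean displacement*: the magnitude of an isotropic Gaussian offset
is Rayleigh distributed with mean $\sigma\sqrt{\pi/2}$, so the per-axis
standard deviation is $\sigma = 10/\sqrt{\pi/2} \approx 7.98$ km. Two
alternative readings — $\sigma = 10$ km per axis, or mean *absolute*
per-axis offset of 10 km — are selectable by configuration, since
verbal descriptions of "average noise" are genuinely ambiguous. On
geographic grids kilometres convert at 111.19 km per degree of latitude
(spherical Earth, radius 6371 km) with east–west offsets scaled by
$\cos(\text{latitude})$ at each point; this is amply accurate at the
10-km scales involved. A point displaced off the study region is
redrawn (up to 100 attempts) rather than reflected or clamped, and
dropped with a warning if no attempt lands — redrawing preserves the
displacement distribution conditional on staying in the region, which
is the natural model for a record that must, after all, have been made
on land.

**Spatially biased loss** draws an anchor point uniformly over the
unmasked study region — uniform over the *region*, not over the data,
because a bias anchor tied to the data would itself be informative —
and removes the `ceiling(fraction * n)` records farthest from it (ties
at the cutoff broken by record id, for determinism). **Random loss**
removes the same number of records uniformly; the pair isolates the
effect of *where* records are lost from *how many*.

**Climate measurement error** perturbs each of the 36 monthly layers
independently. Noise is drawn as independent standard normals at the
nodes of a coarse grid, bicubically interpolated to the fine grid, then
scaled by the per-cell standard-error surface and added to the layer.
The coarse spacings (0.5° for temperature, 0.25° for precipitation, or
their metric equivalents of roughly 55.6 and 27.8 km) are the scales at
which spatial correlation between interpolation errors becomes
negligible; the resulting noise field is almost perfectly correlated at
lags of one fine cell and uncorrelated between nodes two spacings
apart, which is exactly the structure the standard-error surfaces are
meant to describe. The spacings are configuration values: the
convention that they are *spatial* scales (rather than temperature
increments) follows from their role in spatial correlation, and a user
with different error-covariance information can change them freely.
Cross-variable correlation is deliberately not modelled: correlations
between 30-year monthly means are small in the context of their
interpolation errors. Precipitation is clamped at zero and `tmin` at
`tmax` after perturbation, with a warning counting affected cells.

**Model variance** partitions the records into `k = 100` random
segments of near-equal size (sizes differ by at most one) and refits
with each segment held out in turn. When all sources are **combined**,
cross-validation is replaced by an independent random
training–testing split per replicate (training share 0.99, mirroring
the 99% training share of 100-fold cross-validation), because each
replicate already carries different perturbed data; testing sets are
then not mutually exclusive across replicates, which is accepted — the
construction is closer to bootstrapping than to cross-validation.

## Numerical choices

- **Bicubic kernel.** Catmull–Rom, the *interpolating* cubic, rather
  than the approximating cubic B-spline: the error simulation samples
  noise *at* coarse nodes and interpolates *between* them, so
  node-value preservation is the contract the tests can pin down
  (along with exact reproduction of constants and planar ramps, and
  linearity in the input — which makes a zero-SD error simulation an
  exact identity). Edge nodes are replicated outward.
- **Grid conventions.** Square cells only; row 1 is the northern edge;
  cell ownership is half-open `[edge, edge + cell_size)`; two
  geometries must agree in every field to be combinable.
- **Quarters.** Any of the 12 consecutive three-month windows with
  December→January wrap; warmest/coldest selected per cell by mean
  monthly mean temperature, `(tmin + tmax)/2`; ties go to the earliest
  starting window. Annual mean temperature is the mean over months of
  `(tmin + tmax)/2` — the standard bioclim convention, adopted because
  the variable list alone does not fix a formula.
- **Future precipitation deltas** default to relative (ratio)
  anomalies, which cannot drive precipitation negative and behave
  better for skewed fields; additive anomalies (clamped at zero) are
  available by configuration.
- **GeoTIFF support** is a minimal, dependency-free reader/writer for
  single-band uncompressed float32 rasters with the standard
  georeferencing tags and `GDAL_NODATA`; ESRI ASCII grids are the
  text-format alternative. Anything more exotic (compression, tiling,
  reprojection, multi-band) is out of scope.

## The synthetic landscape and what passing tests mean

The generator builds a 100 × 100 cell, 1-km landscape by default:
temperature as a north–south gradient plus an elevation-style lapse
from a smooth random field, sinusoidal seasonality whose amplitude
grows with elevation, a diurnal range tied to an independent smooth
field and widened in the warm season (so the three temperature
predictors are correlated but not collinear), log-normal precipitation
with Gaussian-filter spatial correlation (autocorrelation $e^{-1}$ at
the configured correlation length, 10 km by default), a clustered
coastline mask (15% of cells), and standard-error surfaces that grow
with the local temperature gradient, as interpolation error does in
rough terrain. A virtual species is sampled without replacement with
probability proportional to a known logistic niche (positive true
coefficients on annual mean temperature and annual precipitation,
intercept solved for a 15% mean prevalence), and its truth raster is
retained.

This fixture supports sharp tests: parameter-recovery (fitted
coefficient signs match the generating niche), calibration (realized
mean displacement, per-node noise SD), zero-perturbation reduction to
the baseline map, and the qualitative claims that motivate the
framework — uncertainty is spatially heterogeneous and concentrated at
range margins, blur grows with location-error magnitude, biased loss
shifts predicted area where random loss of the same size does not, and
combined sources disagree at least as much as any single source.

What passing does **not** show: the landscape has no real topography,
no dispersal limitation or biotic structure, its climate fields are far
smoother than real interpolated surfaces, the virtual species obeys the
fitted model family exactly (no model misspecification), and its
records are a random sample of the niche (no observation process beyond
the perturbations being tested). Results on real data inherit none of
these conveniences; the tests validate the *machinery*, not ecological
realism.

Problem sizes in the shipped test-suite: unit oracles run on 3–8 cell
grids; the end-to-end checks use the default 100 × 100 fixture with 300
records and 100 replicates per source, and the statistical
calibrations use 100,000 displaced points and 1,000 error-field
replicates — sizes chosen so the full suite completes in a few minutes
on a single CPU while keeping Monte Carlo error well inside the
asserted tolerances.

## Known limitations

- Only the six bioclim predictors above are derived; the remaining 13
  standard bioclim variables, radiation and moisture indices are not.
- The built-in backend omits MaxEnt's hinge/product/threshold
  features; with strongly non-quadratic true response curves the
  suitability surface is correspondingly smoother than a full MaxEnt
  fit.
- Detectability and misidentification error models are not simulated;
  neither is temporally correlated (interannual) climate noise.
- Error surfaces are inputs (or synthesized); estimating them from
  station data is the job of a thin-plate-spline fitting package, not
  this one.
- Multimodel means across GCMs are intentionally not provided:
  averaging climate futures conceals exactly the spread this package
  exists to display. Run the scenario matrix and look at the maps side
  by side.
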