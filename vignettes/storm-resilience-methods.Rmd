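---
title: "Methods: mapping hurricane damage and mangrove resilience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping hurricane damage and mangrove resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilmap)
```

## The problem

Tropical cyclones damage mangrove forests in two largely independent ways.
Winds strip leaves and snap stems, reducing canopy height and fractional
vegetation cover (FVC); storm surge floods the forest floor, and where the
terrain is hydrologically isolated — low-lying basins enclosed by natural or
artificial berms — the flood water ponds and the forest can fail to recover
entirely (dieback). Distinguishing transient defoliation from incipient
dieback, and attributing each to its physical driver, requires combining
three-dimensional structure change (lidar/stereo canopy height models),
cover change (classified FVC maps), and a greenness time series
(NDVI) that tracks each pixel's recovery trajectory.

resilmap implements that inference chain and ships a synthetic coastal
landscape generator with known ground truth, so that every stage — and the
chain end to end — can be validated quantitatively.

## The inference chain

### Canopy structure

Stereo photogrammetry measures a surface elevation, not a canopy height, so
stereo DSMs are calibrated against lidar canopy heights with a linear
bias-correction equation fitted by OLS on a seeded random sample of forest
pixels (default n = 1000, `fit_bias_correction()`). A linear form is the
minimal defensible model for a single DSM–lidar scatter; the fitted `lm`
object is retained so a richer form can be substituted. Corrected heights
are clipped at zero. Canopy volume is the sum of height times cell area
(`canopy_volume()`), and per-pixel height loss is summarized by five
pre-storm height classes (0–5, 5–10, 10–15, 15–20, >20 m) crossed with six
5 m/s maximum-wind classes (26–30 … >50 m/s), reporting the mean, the
pixel-population standard error, and area per cell (`damage_summary()`).
Pixel-level SEs understate uncertainty because adjacent pixels are not
independent; the summaries are descriptive, and the class comparison is done
with a one-way ANOVA plus Tukey HSD (`anova_tukey()`) whose compact letter
display uses the standard insert-and-absorb algorithm. When the response has
exactly zero variance the F ratio is 0/0; the report carries `NaN` and no
pair is flagged.

All class intervals are left-closed/right-open; the top FVC interval is
closed (100% cover belongs to "80–100%") and the top height and wind
intervals are open above. A value exactly on an interior edge therefore
falls in the upper class.

### Canopy cover

Wall-to-wall FVC maps come from a supervised classifier trained on seeded
stratified samples (default 1000 per class) of composite reflectance
features against lidar-derived FVC classes. One classifier is trained per
epoch — pre-storm features against pre-storm classes, post-storm against
post-storm — because the post-storm scene contains cover classes that barely
exist before the storm. The default backend is a random forest (bag
fraction 0.5); the pipeline uses 100 trees for the FVC stage, since with
only a few spectral features a deeper ensemble is needed to resolve the
rarer classes, while 20 trees remain the interface default for simpler
two-class extent mapping. Zero-variance features are dropped before
training: with random split selection a constant predictor silently degrades
the forest. A deterministic nearest-centroid backend
(`classifier_spec("nearest-centroid")`) is provided as a
library-independent reference and is what the test suite pins its exact
expectations on.

FVC change is expressed in classes: a reduction of *k* classes maps to the
*k*-th 20%-wide drop interval (3 classes lost, e.g. 80–100% down to
20–40%, is a drop of "40–60%"); apparent greening is clipped to "none".
Accuracy is assessed with a stratified error matrix (default 500 points per
reference class) whose overall accuracy is the trace over the total.

### Recovery and resilience

The greenness reference is the per-pixel, per-band median over all valid
observations in a two-year pre-storm window; medians are robust to residual
cloud contamination. NDVI is computed per scene and composited as its own
band. The post-storm state of each pixel is summarized by:

* the **mean NDVI anomaly** over the 15 months after the storm (valid
  observations only), with the **drop** defined on the positive scale as
  minus that mean — the code fixes this one sign convention everywhere;
* the **NDVI slope** over the first full calendar year after the storm
  (excluding the immediate post-storm months, which mix delayed browning
  and standing water into the trend), fitted by per-pixel OLS against time
  in years;
* the **recovery time**: the fitted line is anchored at the slope window's
  end (noise-robust, rather than using the raw last observation) and
  extrapolated to the reference, `t = (ndvi_ref - fitted_end) / slope`.
  A pixel already at or above its reference gets 0 years; a pixel with a
  non-positive slope is never assigned a recovery time, because a flat or
  browning trend does not reach the reference;
* an **observed-recovery flag**: mean anomaly over the final 90 days of the
  slope window at or above zero.

The three-tier classification is applied in a fixed precedence so that it
is total and mutually exclusive:

1. **high** — observed recovery, or predicted recovery within 5 years
   regardless of the drop, or a drop below 0.1 despite at least
   tropical-storm-force winds (the wind guard is configurable; on the
   synthetic coast every pixel qualifies);
2. **low** (dieback) — a drop above 0.2 together with failed recovery
   (predicted recovery beyond 15 years, a non-positive slope, or no
   assigned recovery time);
3. **intermediate** — everything else, which covers predicted recovery
   between 5 and 15 years as well as stalled trends with moderate
   (0.1–0.2) drops.

High precedes low deliberately: fast predicted recovery pre-empts the
drop-based dieback rule, and the small-drop rule is read as a small
*magnitude* of change — the only reading consistent with the rule ordering.
Thresholds (0.1, 0.2 NDVI; 5, 15 yr) are `resilience_thresholds()`
parameters.

### Attribution and stratified statistics

Resilience classes are profiled against ground elevation, surge depth
(water-surface elevation minus ground elevation, clipped at zero), dominant
species and FVC drop: per-class medians, quartiles and empirical CDFs
(`class_distribution()`, CDF bin widths default to 1 cm for elevation and
0.1 m for surge — purely presentational), exceedance fractions, and
area cross-tabs that conserve total area exactly.

Distributional differences between classes are tested with a resampled
two-sample Kolmogorov–Smirnov procedure (`iterated_ks()`): a seeded pool
per class (default 10,000 pixels; smaller classes pool everything, with a
warning), then 5000 iterations each drawing 500 pixels per class — one
pixel draw per class per iteration, shared across all variables — reporting
the mean and quartiles of D against the asymptotic critical value
`c(alpha) * sqrt((n+m)/nm)` with the standard tabulated coefficients
(c(0.05) = 1.358; alphas without a tabulated coefficient are an error).
At n = m = 500 the asymptotic form is accurate; the exact small-sample
distribution is unnecessary. No multiple-testing correction is applied
across the variable-by-pair cells; the report is descriptive and the
per-cell critical value is stated. Percent canopy height loss excludes
pixels below 0.5 m pre-storm height to guard the division.

## The synthetic landscape generator

`simulate_landscape()` builds a coastal scene that reproduces the
*statistical structure* the analysis relies on, not any real geography:

* **Terrain and hydrology** — a smooth elevation gradient rising inland
  from the coast; interior basins (default 30% of the terrain) carved to a
  few cm asl and enclosed by a ~0.5 m berm; basins are `ponded`, everything
  else `drained`. Storm surge (default 3 m at the coast) decays inland but
  stays high enough to overtop berms, so ponded pixels flood >1.4 m deep.
* **Species zonation** — the salt-tolerant basin specialist
  (*A. germinans*) dominates ponded basins; fringe and upland species
  occupy the coastal strip and high ground.
* **Canopy and damage** — taller stands in drained riverine zones (up to
  ~21 m) than in basins (up to ~14 m); height loss is proportional to
  pre-storm height (10–22%, increasing with wind), which yields roughly a
  1.5 m mean loss and a ~16% canopy-volume loss on the default coast.
* **Ground truth** — ponded mangrove pixels are `low`; drained pixels split
  into spatially coherent `intermediate` patches (default 25%) and `high`
  elsewhere. Each class draws its storm-time NDVI drop from its own range
  (high < 0.1, intermediate 0.1–0.2, low > 0.2).
* **Recovery rates** — `high` pixels resprout at the fast drained rate
  (default +0.3 NDVI/yr, i.e. recovered well within the first year);
  `low` pixels keep browning (default −0.05 NDVI/yr). `intermediate`
  pixels draw a per-pixel rate targeting a 6–13 yr predicted recovery: a
  single shared drained rate cannot represent this class, because recovery
  time is deficit over slope and the deficit is fixed by the class's drop
  range. The rate therefore varies by truth class, and this is the one
  place the generator's design departs from a strictly
  drainage-determined rate.
* **Reflectance** — each pixel's NDVI trajectory (stationary reference,
  instantaneous class-dependent drop at the storm date, linear recovery
  capped at full recovery, browning floored at 0.05) plus Gaussian noise
  (default sd 0.02 NDVI) is back-computed into red/NIR pairs with NIR held
  at 0.4, so recomputing the index from the bands is exact. Defoliation
  realizes the same NDVI drop through the linear cover–greenness relation
  (`ndvi_ref = 0.35 + 0.55 fvc`), so post-storm reflectance genuinely
  encodes post-storm cover, clamped where the drop exceeds what the
  standing cover allows. Scene validity is independent
  Bernoulli(1 − cloud_prob) per pixel per scene (default 0.3), the
  simplest null that exercises valid-mask handling.
* **Calendar** — a 16-day revisit from late August 2015 to the end of
  2018 with a 10 September 2017 storm: 77 scenes, about 23/yr, of which
  roughly 14/yr survive the cloud mask.

The pre-storm series is white noise around a constant: no seasonality, no
phenology, no sensor harmonization artifacts, no spatially correlated
clouds, no geolocation error. Passing end-to-end tests on this landscape
therefore demonstrates that the chain's logic and numerics are correct
under its stated assumptions — not that the thresholds would perform
identically on real imagery, where anomaly baselines absorb seasonal
structure and cloud gaps cluster.

One seeded generator drives every stochastic draw; stage-specific streams
are derived deterministically from the master seed, so identical
configurations reproduce identical landscapes byte for byte.

## Numerical choices and degenerate inputs

* Per-pixel OLS slopes are computed in closed form over valid observations;
  fewer than two observations (or zero time spread) give `NA`, and any
  statistic over an all-invalid window is `NA`. Nodata propagates: a stage
  output is `NA` wherever a required input is.
* KS statistics are evaluated at the last occurrence of each distinct value,
  which handles ties within and across samples exactly; the implementation
  agrees with a brute-force ECDF oracle on tied samples and with the
  reference implementation on continuous ones.
* Random-forest vote ties are broken by the RNG; prediction re-seeds it so
  repeated prediction is reproducible.
* Parameter-recovery checks for the bias correction use the joint 95%
  confidence ellipse for (intercept, slope) — the estimates are strongly
  correlated, and the joint region has exact coverage where a box of
  marginal intervals does not.
* Areas are pixel counts times cell area; cross-tabs and class summaries
  conserve totals exactly by construction, and the tests assert it.

## Problem sizes

The default landscape is 200 × 200 pixels at 30 m (3600 ha) with 77
scenes; a full pipeline run, including the 5000-iteration KS comparison,
takes well under a minute on one core. The test suite uses a 50 × 50
landscape for shared fixtures, 500 iterations for KS level checks, 500
replicates for the ANOVA type-I simulation, and 100 seeded replicates for
bias-correction coverage; these sizes give Monte-Carlo error comfortably
inside the asserted bands.

## Known limitations

* All grids are assumed co-registered on one planar grid; reprojection,
  geodesic areas and mosaicking are out of scope. Mixed resolutions are
  supported only through integer block aggregation (`resample_block()`).
* Rasters are exchanged as Esri ASCII grids — plain text, GDAL-readable,
  but without CRS metadata or compression.
* The classifier contract is intentionally narrow (features in, classes
  out); probabilistic outputs and feature engineering beyond composite
  bands and indices are left to the caller.
* The resilience thresholds are fixed inputs, not fitted quantities;
  sensitivity to them should be explored with `resilience_thresholds()`
  rather than inferred from the defaults.
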