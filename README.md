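# resilmap

Storm damage and resilience mapping for coastal mangrove forests.

Hurricanes damage mangroves through two distinct channels: wind strips
canopy (reducing height and fractional vegetation cover, FVC), while storm
surge that ponds in low-lying, hydrologically isolated basins can kill the
forest outright. resilmap implements the full inference chain that separates
the two from remote-sensing inputs — co-registered raster layers (lidar
canopy height models, stereo surface models, elevation, surge, wind,
species) and a satellite reflectance time series — and classifies every
pixel's recovery trajectory into three resilience tiers, where **low**
marks dieback.

The chain, stage by stage:

- **Canopy structure** — stereo-DSM calibration against lidar
  (`chm = a + b * dsm` fitted on a seeded pixel sample), canopy-height
  differencing, canopy volume, and damage summaries by pre-storm height
  class (0–5 … >20 m) crossed with maximum-wind class (26–30 … >50 m/s),
  tested with one-way ANOVA + Tukey HSD and compact letter displays.
- **Canopy cover** — random-forest (or nearest-centroid) FVC
  classification per epoch, and class-change mapping: a reduction of *k*
  FVC classes is a drop of the *k*-th 20% interval (e.g. 80–100% →
  20–40%, three classes, is a "40–60%" drop). Accuracy via stratified
  error matrices.
- **Recovery and resilience** — median composites as the pre-storm NDVI
  reference; the 15-month mean NDVI anomaly (`drop = -anomaly`); the 2018
  NDVI slope; recovery time `t = deficit / slope` (unassigned when the
  slope is non-positive); then the classification — **high** (recovered,
  or predicted `t ≤ 5` yr, or drop < 0.1 under storm winds), **low**
  (drop > 0.2 with `t > 15` yr or a non-positive slope), **intermediate**
  (everything between).
- **Attribution** — resilience classes against elevation, surge depth
  (`max(surge − ground, 0)`), dominant species, and FVC drop; medians,
  empirical CDFs, exceedance fractions and exactly-conserving area
  cross-tabs.
- **Stratified statistics** — a resampled two-sample Kolmogorov–Smirnov
  comparison: pools per class, 5000 iterations of 500 samples per class,
  mean and quartiles of `D = sup |ECDF₁ − ECDF₂|` against the critical
  value `c(α)·√((n+m)/nm)`, `c(0.05) = 1.358`.

A seeded synthetic coastal landscape generator (`simulate_landscape()`)
emulates the structure this analysis depends on — height-dependent wind
damage, basin ponding driving failed recovery, species zonation by
elevation, cloud-gapped scenes — with per-pixel ground truth, so every
stage is validated quantitatively. See the methods vignette
(`vignettes/storm-resilience-methods.Rmd`) for the model, its assumptions
and the design choices.

## Worked example

```r
library(resilmap)

cfg  <- landscape_config(grid_rows = 120, grid_cols = 120, seed = 42)
land <- simulate_landscape(cfg)
land
#> <storm_landscape> 120x120 grid, 13301 mangrove pixels
#> <scene_stack> 14400 pixels x 77 scenes (2015-08-31 .. 2018-12-29), 70% valid

res <- assess_resilience(land$scenes, mask = land$pixels$mangrove)
dplyr::count(res, resilience)
#> # A tibble: 4 × 2
#>   resilience       n
#>   <fct>        <int>
#> 1 low           3416
#> 2 intermediate  1783
#> 3 high          8102
#> 4 <NA>          1099
```

3416 of 13,301 mangrove pixels (307 ha of the 1200-ha mask) are classified
as dieback; the `NA` rows are the non-mangrove pixels outside the mask.
Attribution ties that dieback to topography and flooding:

```r
px <- dplyr::bind_cols(land$pixels,
                       res[, c("drop", "slope", "recovery_time", "resilience")])
px$sdepth <- surge_depth(px$surge_level, px$elevation)
m <- dplyr::filter(px, mangrove, !is.na(resilience))

class_distribution(m, "resilience", "elevation", bin_width = 0.01)$summary
#> # A tibble: 3 × 6
#>   class        median     q1    q3 n_pixels area_ha
#>   <fct>         <dbl>  <dbl> <dbl>    <int>   <dbl>
#> 1 low          0.0954 0.0640 0.128     3416    307.
#> 2 intermediate 0.617  0.323  0.832     1783    160.
#> 3 high         0.804  0.496  1.09      8102    729.

exceedance_fraction(m, "resilience", "sdepth", "low", 1.4)
#> [1] 0.986
```

Dieback pixels sit at a median elevation of ~10 cm asl — an order of
magnitude below the surviving classes — and 98.6% of them were flooded
more than 1.4 m deep. Damage summaries confirm the complementary wind
channel (taller classes lose more height):

```r
head(damage_summary(px, mask = "mangrove"), 4)
#> # A tibble: 4 × 6
#>   height_class wind_class mean_loss_m    se_m n_pixels area_ha
#>   <fct>        <fct>            <dbl>   <dbl>    <int>   <dbl>
#> 1 0-5 m        26-30            0.612 0.0340         6    0.54
#> 2 0-5 m        31-35            0.539 0.00852      236   21.2
#> 3 0-5 m        36-40            0.540 0.00766      312   28.1
#> 4 0-5 m        41-45            0.676 0.0121        98    8.82
```

Against the generator's ground truth, 94.8% of mangrove pixels receive
their true resilience class on this landscape. `run_pipeline()` chains all
of the above (plus FVC change mapping and the iterated KS report) from one
seeded configuration and writes every product with a checksummed manifest;
`plot_resilience_map()`, `autoplot()` and the `tidy()`/`glance()` methods
cover the result types.

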