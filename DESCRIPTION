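Package: resilmap
Title: Storm Damage and Resilience Mapping for Coastal Mangrove Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify hurricane damage to mangrove forests and map
    their recovery from co-registered raster layers and satellite reflectance
    time series. Implements stereo-DSM bias correction against lidar canopy
    heights, canopy-height differencing with class-stratified damage summaries
    (ANOVA and Tukey HSD with compact letter displays), fractional vegetation
    cover (FVC) class-change mapping, NDVI-anomaly-based recovery-time
    estimation with a three-tier resilience classification
    (high/intermediate/low), exposure attribution against elevation, storm
    surge, species and FVC loss, and a resampled two-sample
    Kolmogorov-Smirnov comparison of environmental variables across
    resilience classes. Includes a seeded synthetic coastal landscape
    generator that emulates height-dependent wind damage, basin ponding with
    failed recovery, species zonation by elevation and cloudy scene masks,
    with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
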