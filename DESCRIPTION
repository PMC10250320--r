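Package: borealtrends
Title: Trend Analysis of Tree Cover Across Boreal Biome Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and summarising directional change in
    satellite-derived tree cover across the boreal biome. Implements robust
    per-series trend estimation (Theil-Sen slope with Mann-Kendall testing and
    Yue-Pilon pre-whitening), empirical variogram estimation with exponential,
    Gaussian and spherical model fits for choosing a minimum transect spacing,
    a south-north transect sampling design with 0.05 degree plots and a
    standardized boundary-distance coordinate, disturbance and vegetation
    stratification, binned latitudinal profiles, penalized-smooth profile
    models with transect random effects and exponentially decaying residual
    spatial correlation, and a seeded synthetic landscape generator that
    emulates the statistical structure of continental tree-cover rasters for
    testing the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml,
    mgcv,
    minpack.lm,
    nlme
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
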