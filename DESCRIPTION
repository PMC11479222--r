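Package: vegcv
Title: Vegetation Change Assessment from NDVI Trends and Spatial Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assess grassland vegetation change from monthly NDVI raster time
    series by combining per-pixel trends in growing-season NDVI with trends in
    its local spatial heterogeneity, measured as the coefficient of variation
    within a 3 x 3 moving window. Pixels where both trends are significant are
    classified into six ecological change classes (improving, regrowing, slight,
    medium and severe degradation, desertification) from the signs of the two
    trends and a mean-NDVI threshold. Drivers of change are attributed with
    per-pixel Pearson correlations and stratified random-forest feature
    importance. A fully labelled synthetic-scene simulator provides ground
    truth for end-to-end validation, and a pipeline runner orchestrates the
    whole analysis from a single YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    jsonlite,
    yaml,
    randomForest,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
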