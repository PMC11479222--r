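# vegcv

Grassland vegetation change from NDVI trends **and** the trend of NDVI's
local spatial heterogeneity.

A greening trend alone cannot distinguish genuine recovery from the patchy
greening that accompanies early degradation, and a browning trend alone
cannot separate fragmentation from wholesale collapse to bare soil. `vegcv`
implements an assessment that uses two per-pixel signals jointly:

* the trend of the annual growing-season (May–September) **median NDVI**, and
* the trend of NDVI **spatial heterogeneity**, measured as the coefficient of
  variation CV = *s*/*m* of the 3 × 3 pixel window around each pixel
  (sample standard deviation over window mean of the annual composite).

Each surface gets a per-pixel OLS slope against calendar year with a
two-sided *t*-test (*n* − 2 df). Pixels where **both** trends are
significant (*p* < 0.05) are classified from the two slope signs and the
multi-year mean NDVI against a sparse-vegetation threshold of 0.2:

| NDVI slope | CV slope | mean NDVI | class |
|---|---|---|---|
| + | − | any | improving |
| + | + | < 0.2 | regrowing |
| + | + | ≥ 0.2 | slight degradation |
| − | + | any | medium degradation |
| − | − | ≥ 0.2 | severe degradation |
| − | − | < 0.2 | desertification |

Change is then attributed to six annual drivers — precipitation (Pre), mean
temperature (Temp), relative humidity (RH), SPEI, grazing intensity (Graz)
and population density (Pop) — by per-pixel Pearson correlation summaries
and by per-stratum random-forest regressions (strata = {steppe, meadow} ×
the six classes; up to 10 000 pixel-year samples per stratum; tree count
chosen by cross-validation; importance = mean decrease in impurity,
normalised to sum to 1; fit scored by out-of-bag R²).

Because the real satellite and reanalysis inputs are not redistributable,
the package ships a first-class **synthetic scene simulator** that generates
fully labelled inputs with known ground truth: block-wise NDVI trends, a
tiled zero-mean divergence pattern whose amplitude trend drives the focal-CV
trend independently of the mean trend, drivers on a coarser grid (exercising
the resampling path), road/river lines (exercising the buffer masking) and a
truth raster for end-to-end validation.

## Worked example

```r
library(vegcv)

scene <- build_scene(demo_scenario_specs(0.02), raster_grid(120, 120),
                     2000:2022, seed = 42)
comp  <- growing_season_median(scene$monthly_ndvi)
masks <- build_mask_set(scene$landcover, lines = scene$lines, grid = comp$grid)
cv    <- focal_cv(comp, mask = masks)
cls   <- classify_change(fit_linear_trend(comp),
                         fit_linear_trend(focal_cv(comp, mask = masks)),
                         period_mean(comp))
recovery_rate(cls, scene)$rate
#> [1] 98.28877
summarize_proportions(cls, scene$grassland_type) |>
  dplyr::filter(stratum == "all")
#> # A tibble: 6 × 6
#>   stratum class              count area_km2 percent percent_of_valid
#>   <chr>   <chr>              <int>    <dbl>   <dbl>            <dbl>
#> 1 all     improving            860     53.8    16.2             7.47
#> 2 all     regrowing            623     38.9    11.8             5.41
#> 3 all     slight_degradation   970     60.6    18.3             8.43
#> 4 all     medium_degradation  1026     64.1    19.4             8.91
#> 5 all     severe_degradation   997     62.3    18.8             8.66
#> 6 all     desertification      824     51.5    15.5             7.16
```

98.3% of interior block pixels recover their planted class label; the class
shares reflect the six equal-area blocks (plus edge and mask effects). The
full analysis — composites, CV stack, trends, classification, driver
summaries, correlations, stratified sampling and random-forest importance —
runs from one configuration:

```r
res <- run_pipeline(demo_pipeline_config(seed = 42))
glance(res$importance)      # per-stratum OOB R-squared, n, tree count
autoplot(res$classes)       # change-class map
```

A thin command-line wrapper with per-stage subcommands
(`simulate | composite | heterogeneity | trends | classify | drivers |
run-all`) is installed at `inst/cli/vegcv.R`.

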