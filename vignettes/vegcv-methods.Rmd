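---
title: "Assessing vegetation change from NDVI and its spatial heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing vegetation change from NDVI and its spatial heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegcv)
```

## The model

`vegcv` assesses grassland change on a fixed raster grid from two per-pixel
annual series derived from monthly NDVI:

1. **Greenness**: the median NDVI over the growing-season months
   (May–September by default). The median is robust to the occasional
   cloud-contaminated month; a pixel-year needs at least
   `min_valid_months = 3` valid months, otherwise it is nodata.
2. **Spatial heterogeneity**: the coefficient of variation
   CV = *s*/*m* of the nine annual-composite values in the 3 × 3 window
   centred on the pixel, where *m* is the window mean and *s* the sample
   standard deviation (divisor 8). On a 250 m grid the window spans
   750 × 750 m — nine samples, enough for a stable CV while staying local.
   High CV marks a patchy vegetation/bare-soil mosaic; its change over time
   distinguishes homogenisation from fragmentation.

Both series get an ordinary least-squares slope against calendar year and a
two-sided *t*-test on the slope with *n* − 2 degrees of freedom. No
multiple-testing correction or autocorrelation adjustment is applied; the
*p*-values are per-pixel screening statistics, which is how the
classification consumes them.

A pixel is classified only when **both** trends are significant at
`alpha = 0.05` (the dual-significance gate). The two slope signs and the
multi-year mean NDVI (sparse-vegetation threshold 0.2) then determine one of
six classes: improving (NDVI up, CV down), regrowing (up/up on sparse
ground), slight degradation (up/up on vegetated ground), medium degradation
(down/up), severe degradation (down/down, vegetated) and desertification
(down/down, sparse). The mapping is exhaustive and mutually exclusive over
the dual-significant sign combinations, which the test-suite checks as a
truth table.

Driver attribution has two layers. Pixel-wise Pearson correlations of each
response (NDVI composite, CV) with each of six annual drivers (Pre, Temp,
RH, SPEI, Graz, Pop) are summarised as the percent of valid area significant
and, among significant pixels, the percent positive/negative. Then
dual-significant pixels are crossed with the grassland type (steppe, meadow)
into up to twelve strata; per stratum, a random-forest regression of the
response on the six drivers is fitted on pixel-year samples, its tree count
chosen by k-fold cross-validated MSE, its fit scored by out-of-bag R², and
its factor importances (mean decrease in impurity) normalised to sum to 1.
Climate (Pre + Temp + RH + SPEI) and human (Graz + Pop) shares are the
corresponding importance sums.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `months` | 5–9 | calendar months | growing season of alpine grassland |
| `window` | 3 | pixels | 750 m neighbourhood at 250 m resolution; 9 samples |
| `alpha` | 0.05 | probability | conventional per-pixel screening level |
| `ndvi_threshold` | 0.2 | NDVI | sparse/vegetated divide for the mean surface |
| `min_valid_years` | 15 | years | a 23-year record with a third missing still fits |
| `buffer_distance` | 250 | map units | one pixel: removes windows a road/river contaminates |
| `sample_cap` | 10 000 | pixel-years | stratum cap; ample for a forest, bounds runtime |
| `tree_grid` | 100–800 | trees | candidate forest sizes for cross-validation |
| `epsilon` | 0 | slope units | "unchanged" = literally zero slope, apt for counts |

Boundary and degeneracy conventions, chosen once and tested:

* A mean NDVI exactly at 0.2 counts as vegetated — the sparse classes
  require strictly sub-threshold means.
* A constant series has slope 0 and *p* = 1 (no evidence of change); an
  exact non-constant line has zero residual and *p* = 0. Both cases are
  detected relative to the series' own scale (`1e-12` of its sum of
  squares), so floating-point cancellation cannot produce spurious
  significance.
* Focal windows must be complete: any nodata/masked member, a masked
  centre, or a window leaving the grid yields nodata; windows whose mean is
  at or below `1e-6` are nodata rather than dividing by a near-zero mean.
* Zero-variance series in a correlation yield nodata, not an error.
* Excluded landcover (impervious, water, wetland, glacier) and line buffers
  are removed *before* windowing, so a masked pixel also invalidates its
  neighbours' windows — deliberately, since the mask exists to stop those
  values contaminating the heterogeneity statistic.

An open choice in the heterogeneity definition is the order of compositing
and windowing: CV could be computed per month and then composited. We
compute the annual composite first and take the CV of that surface — one
heterogeneity value per pixel-year, directly parallel to the NDVI series it
is compared with — and treat the alternative as out of scope.

## The synthetic scene generator

Real MODIS-era NDVI, meteorological reanalysis and population/livestock
products cannot ship with a package, so validation runs on simulated scenes
with known truth. Each rectangular block follows

v(t) = (b + a·t) · (1 + o · (d₀ + d₁·t)) + ε,

where *b* is the baseline NDVI, *a* the NDVI trend, *o* the pixel's offset
in a fixed zero-mean 3 × 3 pattern, d₀/d₁ the divergence level and trend,
and ε monthly Gaussian noise (plus a fixed seasonal jitter at half the noise
sd, constant across years so it shifts levels without adding trend noise).
The pattern is tiled periodically, so **every** interior window contains all
nine offsets: in the noiseless case the window mean is exactly the mean
trajectory (the offsets cancel) and the focal CV is exactly
(d₀ + d₁·t) · sd(offsets). The mean trend and the heterogeneity trend are
therefore independently controllable, and every class in the table above can
be planted on demand.

Drivers are simulated on a four-times-coarser grid and brought to the
analysis grid by bilinear (continuous) or nearest (integer counts)
resampling — the same path real driver products take. An optional
`response_link` adds β · (standardised driver) to the NDVI annual signal so
attribution recovery can be tested against a known cause. Population is
integer-valued with a literally zero slope, which is what produces large
"unchanged" fractions under the exact-zero rule.

The bundled demonstration scene (`demo_scenario_specs()`) is 120 × 120
pixels, 23 years, 5 months per year, monthly noise sd 0.02, with one 32 × 32
block per class, a road and a river crossing blocks, and 2% of background
pixels as water/impervious. Block effect sizes were set by an a-priori power
analysis of this generative model: with 23 annual composites the OLS slope
standard error is roughly σ_a/31.8 (σ_a ≈ 0.011, the sd of a median of five
noisy months), and every block's NDVI and CV trends were sized so per-pixel
|t| statistics are ≳ 4 for the weakest pixels. The binding constraints are
the sparse (mean < 0.2) classes: their low mean pushes the CV noise floor
σ_a/m up, so they need large divergence amplitudes, while the per-pixel NDVI
slope a·(1 ± d) ∓ m·d₁ must keep the sign of *a* at every offset, and
off-centre pixels must keep their period mean on the right side of 0.2. The
desertification corner of this trade-off is the hardest; its per-pixel CV
power is the lowest in the scene (roughly nine in ten pixels recovered),
while the other five blocks recover essentially completely, giving ~98%
overall recovery under noise and exactly 100% in the noiseless variant.

What the simulator does **not** emulate: spatial autocorrelation of the
noise field, cloud/QA gaps with seasonal structure, mixed pixels at block
edges, anisotropic heterogeneity (the divergence pattern is isotropic in
distribution), and any mechanistic vegetation or soil response. Passing
tests therefore demonstrate that the estimators and rules recover known
structure under idealised noise — not that the ecological interpretation of
any class is correct for a particular landscape.

## Numerical and design notes

* **Trend and correlation fits are vectorised** over pixels via masked sum
  accumulation; the test-suite pins them to closed-form oracles and to
  `lm()`/`cor.test()` at 1e-10/1e-12.
* **Focal CV** uses shifted-sum accumulation; an explicit per-window
  brute-force oracle checks equality to 1e-12, including masking and border
  behaviour. CV is scale-invariant but not shift-invariant — a test
  documents this deliberately, since it is why the statistic reacts to
  bare-soil contrast.
* **Tree-count cross-validation** fits one forest of `max(tree_grid)` trees
  per fold and scores every candidate count from cumulative per-tree
  predictions — equivalent to refitting at each size, at a fifth of the
  cost. The selected count then refits on the full stratum.
* **Determinism**: every stochastic step (scene noise, landcover scatter,
  driver fields, stratum subsampling, fold assignment, forests) is seeded
  from the configuration; rerunning a configuration reproduces every CSV
  and raster byte for byte.
* **Problem sizes**: the shipped demonstration analysis uses the full
  120 × 120 × 23-year scene for everything through classification, and
  per-stratum caps of 2 000 samples with a 100–300 tree grid for the
  forests — sizes chosen so a complete run stays within a few minutes on a
  single core while leaving every qualitative behaviour intact. The
  paper-scale defaults (cap 10 000, trees up to 800) remain the package
  defaults for real data.

## Limitations

* Per-pixel significance ignores spatial autocorrelation, so area
  percentages of "significant" change are descriptive, not inferential.
* The CV is undefined over near-zero mean windows and unstable over sparse
  ground, where the noise floor σ/m inflates heterogeneity — the reason the
  sparse classes are the hardest to detect, in simulation and presumably in
  reality.
* Importance from impurity is biased toward high-variance continuous
  predictors; with one integer-valued, nearly constant driver (Pop) its
  importance is structurally small. Permutation importance could be added
  as a cross-check.
* Only one CRS is supported; inputs must already share a grid or be
  alignable by resampling.
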