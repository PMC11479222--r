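test_that("noiseless pixel series reproduces the linear annual trajectory", {
  spec <- scenario_spec("improving", c(1, 3, 1, 3), baseline_ndvi = 0.5,
                        ndvi_slope = 0.01, divergence_base = 0.1,
                        divergence_slope = -0.001)
  ser <- simulate_pixel_series(spec, pattern_offset = 0, years = 2000:2022,
                               seed = 3)
  med <- as.numeric(tapply(ser$ndvi, ser$year, stats::median))
  expect_equal(med, 0.5 + 0.01 * (0:22), tolerance = 1e-12)
})

test_that("time-invariant divergence gives a constant window CV over years", {
  spec <- scenario_spec("custom", NULL, baseline_ndvi = 0.4,
                        ndvi_slope = 0.005, divergence_base = 0.1,
                        divergence_slope = 0)
  cv_by_year <- window_cv_by_year(spec, 2000:2010)
  expect_equal(cv_by_year, rep(cv_by_year[1], 11), tolerance = 1e-12)
})

test_that("positive divergence slope makes the window CV strictly increase", {
  # brute-force CV over the nine generated offset series, year by year
  spec <- scenario_spec("custom", NULL, baseline_ndvi = 0.4, ndvi_slope = 0,
                        divergence_base = 0.1, divergence_slope = 0.01)
  cv_by_year <- window_cv_by_year(spec, 2000:2022)
  expect_true(all(diff(cv_by_year) > 0))
  # and it equals divergence(t) * sd(offsets) exactly
  expect_equal(cv_by_year,
               (0.1 + 0.01 * (0:22)) * stats::sd(as.vector(canonical_offsets())),
               tolerance = 1e-12)
})

test_that("a noiseless trajectory leaving [0, 1] is rejected", {
  spec <- scenario_spec("improving", c(1, 3, 1, 3), baseline_ndvi = 0.9,
                        ndvi_slope = 0.02, divergence_base = 0.05,
                        divergence_slope = -0.001)
  expect_error(simulate_pixel_series(spec, 0, 2000:2022, seed = 1),
               "exits")
  expect_error(build_scene(list(spec_with_block(spec, c(1, 6, 1, 6))),
                           raster_grid(10, 10), 2000:2022),
               "exits")
})

test_that("scenario_spec enforces label consistency with parameter signs", {
  expect_error(scenario_spec("regrowing", c(1, 3, 1, 3), 0.5, 0.01, 0.1, 0.01),
               "inconsistent")
  expect_error(scenario_spec("improving", c(1, 3, 1, 3), 0.5, -0.01, 0.1, -0.01),
               "inconsistent")
  expect_silent(scenario_spec("desertification", c(1, 3, 1, 3), 0.15, -0.002,
                              0.1, -0.001))
})

test_that("scenes are deterministic and respect NDVI range and nodata rules", {
  specs <- demo_scenario_specs(0.05)[1:2]
  grid <- raster_grid(50, 80)
  s1 <- build_scene(specs, grid, 2000:2005, seed = 11)
  s2 <- build_scene(specs, grid, 2000:2005, seed = 11)
  expect_identical(s1$monthly_ndvi$values, s2$monthly_ndvi$values)
  expect_identical(s1$drivers$variables, s2$drivers$variables)
  expect_identical(s1$landcover, s2$landcover)
  s3 <- build_scene(specs, grid, 2000:2005, seed = 12)
  expect_false(identical(s1$monthly_ndvi$values, s3$monthly_ndvi$values))
  v <- s1$monthly_ndvi$values
  expect_true(all(v[!is.na(v)] >= -1 & v[!is.na(v)] <= 1))
  # nodata exactly where landcover dictates
  bad <- s1$landcover %in% c("water", "impervious")
  expect_true(all(is.na(v[, , 1][bad])))
  expect_false(anyNA(v[, , 1][!bad]))
  # truth defined for every non-nodata pixel
  expect_false(anyNA(s1$truth$labels[!bad]))
})

test_that("noiseless scenes satisfy the label-consistency sign invariant", {
  specs <- demo_scenario_specs(0)
  # shrink blocks onto a small grid for speed
  blocks <- list(c(2, 13, 2, 13), c(2, 13, 17, 28), c(17, 28, 2, 13),
                 c(17, 28, 17, 28))
  specs <- purrr::map2(specs[c(1, 2, 4, 6)], blocks, spec_with_block)
  scene <- build_scene(specs, raster_grid(30, 30), 2000:2022, seed = 5,
                       water_fraction = 0)
  comp <- growing_season_median(scene$monthly_ndvi)
  tn <- fit_linear_trend(comp)
  cv <- focal_cv(comp)
  tc <- fit_linear_trend(cv)
  for (sp in specs) {
    b <- sp$block
    sl <- tn$slope[b[1]:b[2], b[3]:b[4]]
    expect_true(all(sign(sl) == sign(sp$ndvi_slope)),
                label = paste("NDVI slope sign in", sp$class_label))
    slc <- tc$slope[(b[1] + 1):(b[2] - 1), (b[3] + 1):(b[4] - 1)]
    expect_true(all(sign(slc) == sign(sp$divergence_slope)),
                label = paste("CV slope sign in", sp$class_label))
  }
})

test_that("build_scene rejects overlapping blocks and too-short year lists", {
  sp <- demo_scenario_specs(0)[[1]]
  a <- spec_with_block(sp, c(1, 10, 1, 10))
  b <- spec_with_block(sp, c(5, 15, 5, 15))
  expect_error(build_scene(list(a, b), raster_grid(20, 20), 2000:2010),
               "overlapping")
  expect_error(build_scene(list(a), raster_grid(20, 20), 2000:2001),
               "shorter than 3")
})

test_that("driver simulation honours exact trends and integer counts", {
  grid <- raster_grid(16, 16)
  links <- default_driver_links()
  links$Temp$sd <- 0
  drv <- simulate_drivers(grid, 2000:2010, links = links, seed = 2)
  trends <- lapply(c(Temp = "Temp", Pop = "Pop"), function(v) {
    fit_linear_trend(annual_stack(grid, 2000:2010, drv$variables[[v]]),
                     min_valid_years = 3, variable = v)
  })
  summ <- driver_trend_summary(trends, epsilon = 0)
  expect_equal(summ$increase[summ$variable == "Temp"], 100)
  # Pop: integer counts, zero slope -> 100% unchanged under the exact-zero rule
  expect_equal(summ$unchanged[summ$variable == "Pop"], 100)
  expect_error(simulate_drivers(grid, 2000:2010,
                                links = list(Bogus = list(mean = 0, slope = 0, sd = 1))),
               "unknown variable")
  links$Pre$sd <- -1
  expect_error(simulate_drivers(grid, 2000:2010, links = links), "negative sd")
})

test_that("a response link makes the perturbation track the named driver", {
  grid <- raster_grid(12, 12)
  drv <- simulate_drivers(grid, 2000:2010, response_link = c(Temp = 0.05),
                          seed = 9)
  pert <- attr(drv, "perturbation")
  expect_s3_class(pert, "annual_stack")
  z <- drv$variables$Temp
  expect_equal(pert$values, 0.05 * (z - mean(z)) / stats::sd(z),
               tolerance = 1e-12)
})

test_that("scene writing round-trips the NDVI stack and truth labels", {
  dir <- withr::local_tempdir()
  scene <- build_scene(demo_scenario_specs(0.02)[1:2], raster_grid(46, 80),
                       2000:2004, seed = 3)
  write_scene(scene, dir)
  back <- read_stack(file.path(dir, "ndvi", "ndvi_manifest.json"))
  expect_equal(back$values, scene$monthly_ndvi$values)
  expect_identical(back$index, scene$monthly_ndvi$index)
  manifest <- jsonlite::read_json(file.path(dir, "scene_manifest.json"))
  expect_equal(manifest$seed, 3)
  expect_length(manifest$specs, 2)
})
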