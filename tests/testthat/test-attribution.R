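test_that("pixelwise Pearson matches cor.test and handles exact correlation", {
  grid <- raster_grid(4, 4)
  years <- 2000:2022
  withr::with_seed(2, {
    resp <- array(stats::rnorm(16 * 23, 0.4, 0.1), dim = c(4, 4, 23))
    drv <- array(stats::rnorm(16 * 23, 10, 2), dim = c(4, 4, 23))
  })
  drv[1, 1, ] <- resp[1, 1, ]            # r = 1
  drv[1, 2, ] <- -resp[1, 2, ]           # r = -1
  drv[1, 3, ] <- 5                       # zero variance
  resp[1, 4, c(1, 5, 9)] <- NA           # gaps
  st <- annual_stack(grid, years, resp)
  pr <- pixelwise_pearson(st, drv)
  expect_equal(pr$r[1, 1], 1)
  expect_equal(pr$p_value[1, 1], 0)
  expect_equal(pr$r[1, 2], -1)
  expect_true(is.na(pr$r[1, 3]))
  for (i in 2:4) for (j in 1:4) {
    ct <- stats::cor.test(resp[i, j, ], drv[i, j, ])
    expect_equal(pr$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p_value[i, j], ct$p.value, tolerance = 1e-12)
  }
  ok <- stats::complete.cases(resp[1, 4, ], drv[1, 4, ])
  ct <- stats::cor.test(resp[1, 4, ok], drv[1, 4, ok])
  expect_equal(pr$r[1, 4], unname(ct$estimate), tolerance = 1e-12)
})

test_that("correlation summaries keep exact sign bookkeeping", {
  grid <- raster_grid(10, 10)
  years <- 2000:2009
  withr::with_seed(5, {
    resp <- array(stats::rnorm(1000, 0.4, 0.1), dim = c(10, 10, 10))
    vars <- lapply(stats::setNames(driver_names(), driver_names()),
                   function(v) array(stats::rnorm(1000), dim = c(10, 10, 10)))
  })
  # one driver perfectly tracks the response -> 100% significant positive
  vars$Temp <- resp
  drv <- driver_stack(grid, years, vars)
  summ <- summarize_correlations(list(NDVI = annual_stack(grid, years, resp)),
                                 drv)
  tt <- summ[summ$variable == "Temp", ]
  expect_equal(tt$percent_significant, 100)
  expect_equal(tt$percent_positive_among_significant, 100)
  sig <- summ[!is.na(summ$percent_positive_among_significant), ]
  expect_equal(sig$percent_positive_among_significant +
                 sig$percent_negative_among_significant,
               rep(100, nrow(sig)), tolerance = 1e-9)
  # a constant driver has no defined correlations anywhere
  vars$Pop <- array(7, dim = c(10, 10, 10))
  summ2 <- summarize_correlations(list(NDVI = annual_stack(grid, years, resp)),
                                  driver_stack(grid, years, vars))
  pop <- summ2[summ2$variable == "Pop", ]
  expect_equal(pop$percent_significant, 0)
  expect_true(is.na(pop$percent_positive_among_significant))
})

test_that("strata sampling caps, reproduces and keeps small strata whole", {
  grid <- raster_grid(40, 40)
  years <- 2000:2019
  # one big stratum (improving steppe) and one small (regrowing meadow)
  labels <- matrix("improving", 40, 40)
  labels[1:2, 1:5] <- "regrowing"
  gl <- matrix("steppe", 40, 40); gl[1:2, 1:5] <- "meadow"
  cl <- make_class_raster(grid, labels)
  withr::with_seed(3, {
    resp <- array(stats::runif(40 * 40 * 20, 0.2, 0.8), dim = c(40, 40, 20))
    vars <- lapply(stats::setNames(driver_names(), driver_names()),
                   function(v) array(stats::rnorm(40 * 40 * 20), dim = c(40, 40, 20)))
  })
  resp[3, 3, 1] <- NA  # one incomplete pixel-year row must be dropped
  responses <- list(NDVI = annual_stack(grid, years, resp),
                    CV = annual_stack(grid, years, resp))
  drv <- driver_stack(grid, years, vars)
  tab <- extract_strata_samples(cl, gl, responses, drv, sample_cap = 10000,
                                seed = 99)
  counts <- table(tab$stratum)
  expect_equal(unname(counts[["steppe.improving"]]), 10000)  # capped exactly
  expect_equal(unname(counts[["meadow.regrowing"]]), 10 * 20) # kept whole
  expect_false(any(tab$pixel_id == 3 + 40 * 2 & tab$year == 2000))
  tab2 <- extract_strata_samples(cl, gl, responses, drv, sample_cap = 10000,
                                 seed = 99)
  expect_identical(tab, tab2)
  tab3 <- extract_strata_samples(cl, gl, responses, drv, sample_cap = 10000,
                                 seed = 100)
  expect_false(identical(tab$pixel_id, tab3$pixel_id))
  # rows carry the dual-significant labels only
  expect_setequal(unique(tab$class), c("improving", "regrowing"))
  # pixel unit averages over years
  tabp <- extract_strata_samples(cl, gl, responses, drv, sample_cap = 1e6,
                                 seed = 1, unit = "pixel")
  expect_equal(nrow(tabp[tabp$stratum == "meadow.regrowing", ]), 10)
})

test_that("random-forest importance recovers a planted driver", {
  n <- 600
  X <- random_driver_df(n, seed = 41)
  withr::with_seed(42, {
    y <- 2 * X$Temp + stats::rnorm(n, 0, 0.1 * stats::sd(X$Temp))
  })
  samples <- synthetic_sample_table(n, y, X)
  imp <- fit_importance(samples, "ndvi", tree_grid = c(100, 200),
                        cv_folds = 3, seed = 7)
  expect_s3_class(imp, "importance_table")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-6)
  expect_identical(imp$factor[which.max(imp$importance)], "Temp")
  expect_gt(imp$r_squared[1], 0.8)
  expect_true(all(imp$n_trees %in% c(100, 200)))
  # broom-style accessors
  expect_named(tidy(imp), c("response", "stratum", "factor", "importance"))
  g <- glance(imp)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_samples, n)
})

test_that("importance fits are seeded-reproducible and guard degenerate input", {
  n <- 120
  X <- random_driver_df(n, seed = 4)
  y <- stats::rnorm(n)
  samples <- synthetic_sample_table(n, y, X)
  i1 <- fit_importance(samples, "ndvi", tree_grid = 100, cv_folds = 2, seed = 5)
  i2 <- fit_importance(samples, "ndvi", tree_grid = 100, cv_folds = 2, seed = 5)
  expect_identical(i1, i2)
  # constant response and under-sized strata are skipped with warnings
  const <- synthetic_sample_table(n, rep(1, n), X)
  expect_warning(out <- fit_importance(const, "ndvi", tree_grid = 100,
                                       cv_folds = 2, seed = 1),
                 "constant")
  expect_equal(nrow(out), 0)
  small <- synthetic_sample_table(10, y[1:10], X[1:10, ])
  expect_warning(fit_importance(small, "ndvi", tree_grid = 100, cv_folds = 2,
                                seed = 1), "skipped")
})

test_that("climate and human shares aggregate importances exactly", {
  eq <- tibble::tibble(response = "ndvi", stratum = "s",
                       factor = driver_names(), importance = rep(1 / 6, 6))
  out <- aggregate_contributions(eq)
  expect_equal(out$climate_share[out$stratum == "s"], 100 * 4 / 6,
               tolerance = 1e-9)
  expect_equal(out$human_share[out$stratum == "s"], 100 * 2 / 6,
               tolerance = 1e-9)
  one <- eq; one$importance <- c(0, 1, 0, 0, 0, 0)  # all weight on Temp
  expect_equal(aggregate_contributions(one)$climate_share[1], 100)
  withr::with_seed(6, {
    w <- stats::runif(6); w <- w / sum(w)
  })
  rnd <- eq; rnd$importance <- w
  out3 <- aggregate_contributions(rnd)
  expect_equal(out3$climate_share[1], 100 * sum(w[1:4]), tolerance = 1e-12)
  expect_equal(out3$climate_share + out3$human_share, rep(100, nrow(out3)),
               tolerance = 1e-9)
})
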