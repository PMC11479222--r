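test_that("linear trends: exact lines, constants and the closed-form oracle", {
  grid <- raster_grid(5, 5)
  years <- 2000:2022
  t <- years - 2000
  vals <- array(NA_real_, dim = c(5, 5, 23))
  withr::with_seed(17, {
    series <- lapply(1:25, function(i) 0.4 + stats::rnorm(23, 0, 0.05))
  })
  for (i in 1:25) vals[arrayInd(i, c(5, 5))[1], arrayInd(i, c(5, 5))[2], ] <- series[[i]]
  vals[1, 1, ] <- 0.2 + 0.01 * t          # exact line
  vals[1, 2, ] <- 0.37                    # constant
  vals[1, 3, c(2, 9)] <- NA               # gaps are skipped
  tr <- fit_linear_trend(annual_stack(grid, years, vals))
  expect_equal(tr$slope[1, 1], 0.01, tolerance = 1e-12)
  expect_lt(tr$p_value[1, 1], 1e-10)
  expect_equal(tr$slope[1, 2], 0)
  expect_equal(tr$p_value[1, 2], 1)       # no-change convention
  for (i in setdiff(3:25, 6)) {  # pixel (1,2) is the constant case above
    rc <- arrayInd(i, c(5, 5))
    o <- ols_oracle(vals[rc[1], rc[2], ], years)
    expect_equal(tr$slope[rc[1], rc[2]], o$slope, tolerance = 1e-10)
    expect_equal(tr$p_value[rc[1], rc[2]], o$p, tolerance = 1e-10)
  }
  expect_equal(tr$n_years[1, 3], 21L)
  # lm() agrees as a second, independent route
  fit <- stats::lm(vals[2, 2, ] ~ years)
  expect_equal(tr$slope[2, 2], unname(stats::coef(fit)[2]), tolerance = 1e-10)
  expect_equal(tr$p_value[2, 2],
               summary(fit)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("short or empty series produce nodata or errors", {
  grid <- raster_grid(2, 2)
  vals <- array(NA_real_, dim = c(2, 2, 23))
  vals[1, 1, 1:10] <- stats::runif(10)
  vals[2, 2, ] <- stats::runif(23)
  tr <- fit_linear_trend(annual_stack(grid, 2000:2022, vals),
                         min_valid_years = 15)
  expect_true(is.na(tr$slope[1, 1]))
  expect_false(is.na(tr$slope[2, 2]))
  empty <- annual_stack(grid, 2000:2002, array(NA_real_, dim = c(2, 2, 3)))
  expect_error(fit_linear_trend(empty), "all-nodata")
})

test_that("the six-class rules map every sign/threshold combination correctly", {
  grid <- raster_grid(1, 1)
  cases <- list(
    list(mu = 0.15, sn = -0.002, pn = 0.01, sc = -0.001, pc = 0.02,
         want = "desertification"),
    list(mu = 0.45, sn = 0.003, pn = 0.001, sc = -0.001, pc = 0.04,
         want = "improving"),
    list(mu = 0.45, sn = 0.003, pn = 0.001, sc = 0.001, pc = 0.2,
         want = "not_significant"),
    list(mu = 0.15, sn = 0.003, pn = 0.01, sc = 0.002, pc = 0.01,
         want = "regrowing"),
    list(mu = 0.45, sn = 0.003, pn = 0.01, sc = 0.002, pc = 0.01,
         want = "slight_degradation"),
    list(mu = 0.45, sn = -0.003, pn = 0.01, sc = 0.002, pc = 0.01,
         want = "medium_degradation"),
    list(mu = 0.45, sn = -0.003, pn = 0.01, sc = -0.002, pc = 0.01,
         want = "severe_degradation"),
    # boundary: mean exactly at the threshold counts as vegetated
    list(mu = 0.2, sn = -0.003, pn = 0.01, sc = -0.002, pc = 0.01,
         want = "severe_degradation"),
    list(mu = 0.2, sn = 0.003, pn = 0.01, sc = 0.002, pc = 0.01,
         want = "slight_degradation"))
  for (cs in cases) {
    cl <- classify_change(make_trend(grid, cs$sn, cs$pn, "NDVI"),
                          make_trend(grid, cs$sc, cs$pc, "CV"),
                          make_mean_surface(grid, cs$mu))
    expect_identical(cl$labels[1, 1], cs$want)
  }
})

test_that("the classification partitions all dual-significant sign combinations", {
  grid <- raster_grid(1, 1)
  six <- setdiff(change_class_levels(), "not_significant")
  seen <- character()
  for (sn in c(-1, 1) * 1e-3) for (sc in c(-1, 1) * 1e-3) {
    for (mu in c(0.1, 0.5)) {
      cl <- classify_change(make_trend(grid, sn, 0.01, "NDVI"),
                            make_trend(grid, sc, 0.01, "CV"),
                            make_mean_surface(grid, mu))
      lab <- cl$labels[1, 1]
      expect_true(lab %in% six)
      seen <- c(seen, lab)
    }
  }
  # exhaustive: all six classes occur over the 8 combinations;
  # improving and medium_degradation ignore the threshold, hence twice
  expect_setequal(unique(seen), six)
  expect_equal(sum(seen == "improving"), 2)
  expect_equal(sum(seen == "medium_degradation"), 2)
})

test_that("missing inputs are nodata and alpha tightening is monotone", {
  grid <- raster_grid(10, 10)
  withr::with_seed(33, {
    sn <- stats::rnorm(100, 0, 1e-3); pn <- stats::runif(100)
    sc <- stats::rnorm(100, 0, 1e-3); pc <- stats::runif(100)
  })
  tn <- make_trend(grid, sn, pn, "NDVI"); tc <- make_trend(grid, sc, pc, "CV")
  mu <- make_mean_surface(grid, 0.4)
  tc$slope[1, 1] <- NA; tc$p_value[1, 1] <- NA
  cl05 <- classify_change(tn, tc, mu, alpha = 0.05)
  expect_true(is.na(cl05$labels[1, 1]))
  cl01 <- classify_change(tn, tc, mu, alpha = 0.01)
  moved <- cl05$labels == "not_significant" & !is.na(cl05$labels) &
    cl01$labels != "not_significant" & !is.na(cl01$labels)
  expect_false(any(moved))
  expect_error(classify_change(tn, tc, mu, alpha = 1.5), "alpha")
  other <- make_trend(raster_grid(9, 9), 0, 1, "CV")
  expect_error(classify_change(tn, other, mu), "grid mismatch")
})

test_that("proportion tables match a direct counting oracle and sum to 100", {
  grid <- raster_grid(10, 10)
  six <- setdiff(change_class_levels(), "not_significant")
  withr::with_seed(12, {
    labels <- sample(c(six, "not_significant", NA), 100, replace = TRUE)
    gl <- matrix(sample(c("steppe", "meadow", "other"), 100, replace = TRUE),
                 10, 10)
  })
  cl <- make_class_raster(grid, labels)
  tab <- summarize_proportions(cl, gl)
  for (st in c("all", "steppe", "meadow")) {
    sel <- if (st == "all") rep(TRUE, 100) else as.vector(gl) == st
    lv <- labels[sel]
    n_sig <- sum(!is.na(lv) & lv != "not_significant")
    sub <- tab[tab$stratum == st, ]
    expect_equal(sub$count,
                 as.integer(table(factor(lv[!is.na(lv) & lv != "not_significant"],
                                         levels = six))))
    expect_equal(sum(sub$percent), 100, tolerance = 0.1)
    expect_equal(sub$area_km2, sub$count * (250 / 1000)^2)
    expect_equal(sub$percent, 100 * sub$count / n_sig)
  }
  # empty significant set: zero counts, zero percents
  cl0 <- make_class_raster(grid, rep("not_significant", 100))
  tab0 <- summarize_proportions(cl0)
  expect_equal(sum(tab0$count), 0)
  expect_equal(sum(tab0$percent), 0)
})

test_that("driver trend direction shares match a counting oracle", {
  grid <- raster_grid(8, 8)
  withr::with_seed(9, {
    s <- stats::rnorm(64, 0, 1); p <- stats::runif(64)
  })
  s[1:5] <- 0
  tr <- make_trend(grid, s, p, "Pre")
  out <- driver_trend_summary(list(tr), epsilon = 0, alpha = 0.05)
  expect_equal(out$increase, 100 * mean(s > 0))
  expect_equal(out$decrease, 100 * mean(s < 0))
  expect_equal(out$unchanged, 100 * mean(s == 0))
  expect_equal(out$significant_increase, 100 * mean(s > 0 & p < 0.05))
  expect_equal(out$increase + out$decrease + out$unchanged, 100)
  # epsilon dead-band
  out2 <- driver_trend_summary(list(tr), epsilon = 0.5)
  expect_equal(out2$unchanged, 100 * mean(abs(s) <= 0.5))
  expect_error(driver_trend_summary(list(tr), epsilon = -1), ">= 0")
})
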