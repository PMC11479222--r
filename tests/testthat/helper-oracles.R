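# Independent oracles and small fixture builders shared across the suite.
# Every oracle deliberately takes a different computational path from the
# implementation it checks.

# Brute-force focal CV: explicit per-window loop, sample sd via stats::sd.
brute_force_cv <- function(composite, mask = NULL, window = 3,
                           mean_floor = 1e-6) {
  grid <- composite$grid
  h <- (window - 1) / 2
  out <- array(NA_real_, dim = dim(composite$values))
  for (k in seq_along(composite$years)) {
    v <- composite$values[, , k]
    if (!is.null(mask)) v[mask$combined] <- NA
    for (i in (1 + h):(grid$n_rows - h)) {
      for (j in (1 + h):(grid$n_cols - h)) {
        w <- v[(i - h):(i + h), (j - h):(j + h)]
        if (any(is.na(w)) || is.na(v[i, j])) next
        m <- mean(w)
        if (m <= mean_floor) next
        out[i, j, k] <- stats::sd(as.vector(w)) / m
      }
    }
  }
  out
}

# Vectorised brute-force focal CV used for larger oracle-equivalence sweeps:
# gathers each 3x3 window into 9 explicit columns, then sample sd / mean.
brute_force_cv_fast <- function(composite, window = 3, mean_floor = 1e-6) {
  grid <- composite$grid
  h <- (window - 1) / 2
  nr <- grid$n_rows; nc <- grid$n_cols
  ii <- rep((1 + h):(nr - h), times = nc - 2 * h)
  jj <- rep((1 + h):(nc - h), each = nr - 2 * h)
  out <- array(NA_real_, dim = dim(composite$values))
  offsets <- expand.grid(dr = -h:h, dc = -h:h)
  for (k in seq_along(composite$years)) {
    v <- composite$values[, , k]
    W <- sapply(seq_len(nrow(offsets)), function(o) {
      v[cbind(ii + offsets$dr[o], jj + offsets$dc[o])]
    })
    m <- rowMeans(W)
    s <- sqrt(rowSums((W - m)^2) / (ncol(W) - 1))
    cv <- s / m
    cv[m <= mean_floor | rowSums(is.na(W)) > 0] <- NA
    out[cbind(ii, jj, k)] <- cv
  }
  out
}

# Closed-form OLS slope and two-sided p for one series (textbook sums).
ols_oracle <- function(y, x) {
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  res <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, p = 2 * stats::pt(-abs(t), n - 2))
}

rand_annual_stack <- function(n_rows, n_cols, years, seed, lo = 0.05, hi = 0.9) {
  withr::with_seed(seed, {
    vals <- array(stats::runif(n_rows * n_cols * length(years), lo, hi),
                  dim = c(n_rows, n_cols, length(years)))
  })
  annual_stack(raster_grid(n_rows, n_cols), years, vals)
}

# Trend surface with prescribed slope/p rasters, for classification tests.
make_trend <- function(grid, slope, p, variable = "x") {
  structure(list(grid = grid, variable = variable,
                 slope = matrix(slope, grid$n_rows, grid$n_cols),
                 p_value = matrix(p, grid$n_rows, grid$n_cols),
                 n_years = matrix(23L, grid$n_rows, grid$n_cols)),
            class = "trend_surface")
}

make_mean_surface <- function(grid, values) {
  structure(list(grid = grid,
                 values = matrix(values, grid$n_rows, grid$n_cols)),
            class = "mean_ndvi_surface")
}

make_class_raster <- function(grid, labels) {
  structure(list(grid = grid,
                 labels = matrix(labels, grid$n_rows, grid$n_cols)),
            class = "change_class_raster")
}

# Sample table with one stratum for direct importance fits.
synthetic_sample_table <- function(n, response, drivers_df,
                                   stratum = "steppe.improving") {
  tibble::tibble(
    pixel_id = seq_len(n), stratum = stratum,
    grassland = sub("\\..*", "", stratum),
    class = sub(".*\\.", "", stratum),
    year = 2000L, response_ndvi = response, response_cv = response) |>
    dplyr::bind_cols(drivers_df)
}

# Random driver design matrix for importance tests.
random_driver_df <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::as_tibble(stats::setNames(
      lapply(driver_names(), function(v) stats::rnorm(n)), driver_names()))
  })
}

# Rebuild a scenario spec on a different block extent.
spec_with_block <- function(spec, block) {
  scenario_spec(spec$class_label, block, spec$baseline_ndvi, spec$ndvi_slope,
                spec$divergence_base, spec$divergence_slope, spec$noise_sd,
                spec$grassland)
}

# Year-by-year CV of a window built from the canonical 9-offset pattern,
# each offset series generated independently by simulate_pixel_series.
window_cv_by_year <- function(spec, years) {
  offs <- as.vector(canonical_offsets())
  meds <- sapply(offs, function(o) {
    ser <- simulate_pixel_series(spec, o, years, seed = 1)
    tapply(ser$ndvi, ser$year, stats::median)
  })
  as.numeric(apply(meds, 1, function(w) stats::sd(w) / mean(w)))
}
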