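#' Six vegetation change classes plus the not-significant label
#' @return Character vector of class labels in legend order.
#' @export
change_class_levels <- function() {
  c("improving", "regrowing", "slight_degradation", "medium_degradation",
    "severe_degradation", "desertification", "not_significant")
}

#' Integer legend used when class rasters are written to file
#' @return Named integer vector (`not_significant` = 0, classes 1..6).
#' @export
change_class_codes <- function() {
  stats::setNames(c(1:6, 0), change_class_levels())
}

#' Per-pixel linear trend with significance
#'
#' Ordinary least-squares slope of the annual value on calendar year, with a
#' two-sided t-test on the slope (n-2 degrees of freedom). Years with nodata
#' are skipped pixel by pixel; a pixel with fewer than `min_valid_years`
#' valid years (never below 3) gets nodata. A perfectly constant series has
#' zero slope and no evidence of change, so its p-value is reported as 1;
#' a noiseless non-constant linear series has zero residual and p = 0.
#'
#' @param stack An [annual_stack()] (NDVI composites, CV surfaces or an
#'   annual driver variable).
#' @param min_valid_years Minimum valid years per pixel (default 15).
#' @param variable Name recorded on the result.
#' @return An object of class `trend_surface` with fields `grid`,
#'   `variable`, `slope`, `p_value` and `n_years` (matrices).
#' @export
fit_linear_trend <- function(stack, min_valid_years = 15, variable = "value") {
  stopifnot(inherits(stack, "annual_stack"))
  grid <- stack$grid
  np <- grid$n_rows * grid$n_cols
  ny <- length(stack$years)
  V <- matrix(stack$values, nrow = np, ncol = ny)
  M <- !is.na(V)
  if (!any(M)) stop("all-nodata stack: nothing to fit", call. = FALSE)
  V0 <- ifelse(M, V, 0)
  x <- as.numeric(stack$years)
  n <- rowSums(M)
  Sx <- as.vector(M %*% x)
  Sxx <- as.vector(M %*% x^2)
  Sy <- rowSums(V0)
  Sxy <- as.vector(V0 %*% x)
  Syy <- rowSums(V0^2)
  sxx <- Sxx - Sx^2 / n          # centred sums
  sxy <- Sxy - Sx * Sy / n
  syy <- Syy - Sy^2 / n
  slope <- sxy / sxx
  sse <- pmax(syy - slope^2 * sxx, 0)
  df <- n - 2
  se <- sqrt(sse / df / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero-variance conventions, judged relative to the series' own scale so
  # float cancellation cannot leak through: a constant series shows no
  # change (p = 1); an exact non-constant line has zero residual (p = 0)
  tol <- 1e-12 * pmax(Syy, .Machine$double.xmin)
  const <- syy <= tol
  slope[const & is.finite(slope)] <- 0
  p[const] <- 1
  zero_res <- !const & (sse <= tol | se == 0)
  p[zero_res] <- 0
  bad <- n < max(3, min_valid_years) | !is.finite(slope)
  slope[bad] <- NA_real_
  p[bad] <- NA_real_
  structure(list(grid = grid, variable = variable,
                 slope = matrix(slope, grid$n_rows, grid$n_cols),
                 p_value = matrix(p, grid$n_rows, grid$n_cols),
                 n_years = matrix(as.integer(n), grid$n_rows, grid$n_cols)),
            class = "trend_surface")
}

#' Assemble a trend surface from its component rasters
#'
#' Mostly useful when slope and p-value rasters come back from disk and need
#' to re-enter [classify_change()] or [driver_trend_summary()].
#'
#' @param grid A [raster_grid()].
#' @param slope,p_value Numeric matrices conforming to `grid`.
#' @param n_years Integer matrix of valid years per pixel (scalar recycled).
#' @param variable Variable name.
#' @return A `trend_surface`.
#' @export
trend_surface <- function(grid, slope, p_value, n_years = NA_integer_,
                          variable = "value") {
  check_raster_conforms(slope, grid, "slope")
  check_raster_conforms(p_value, grid, "p_value")
  if (length(n_years) == 1) {
    n_years <- matrix(as.integer(n_years), grid$n_rows, grid$n_cols)
  }
  structure(list(grid = grid, variable = variable, slope = slope,
                 p_value = p_value, n_years = n_years),
            class = "trend_surface")
}

#' @export
print.trend_surface <- function(x, ...) {
  cat(sprintf("<trend_surface> '%s', %d x %d pixels, %d with a fit\n",
              x$variable, x$grid$n_rows, x$grid$n_cols, sum(!is.na(x$slope))))
  invisible(x)
}

#' Classify vegetation change from dual NDVI and heterogeneity trends
#'
#' A pixel enters classification only if both its NDVI trend and its focal-CV
#' trend are significant (`p < alpha`); everything else that carries data is
#' `not_significant`. Significant pixels map to six classes from the two
#' slope signs and the multi-year mean NDVI against the sparse-vegetation
#' threshold (default 0.2):
#'
#' * NDVI up, CV down: `improving`
#' * NDVI up, CV up, mean below threshold: `regrowing`
#' * NDVI up, CV up, mean at/above threshold: `slight_degradation`
#' * NDVI down, CV up: `medium_degradation`
#' * NDVI down, CV down, mean at/above threshold: `severe_degradation`
#' * NDVI down, CV down, mean below threshold: `desertification`
#'
#' A mean NDVI exactly at the threshold counts as vegetated (the sparse
#' classes require strictly sub-threshold means). Pixels with a zero
#' significant slope cannot occur (zero slope implies p = 1).
#'
#' @param ndvi_trend,cv_trend [fit_linear_trend()] surfaces on one grid.
#' @param mean_ndvi A [period_mean()] surface.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param ndvi_threshold Sparse-vegetation mean-NDVI threshold, default 0.2.
#' @return An object of class `change_class_raster` with fields `grid` and
#'   `labels` (character matrix over [change_class_levels()] or `NA`).
#' @export
classify_change <- function(ndvi_trend, cv_trend, mean_ndvi, alpha = 0.05,
                            ndvi_threshold = 0.2) {
  stopifnot(inherits(ndvi_trend, "trend_surface"),
            inherits(cv_trend, "trend_surface"),
            inherits(mean_ndvi, "mean_ndvi_surface"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  stop_if_grid_mismatch(ndvi_trend$grid, cv_trend$grid, "trend surfaces")
  stop_if_grid_mismatch(ndvi_trend$grid, mean_ndvi$grid, "trend and mean surfaces")
  grid <- ndvi_trend$grid
  sn <- ndvi_trend$slope; pn <- ndvi_trend$p_value
  sc <- cv_trend$slope;  pc <- cv_trend$p_value
  mu <- mean_ndvi$values
  # classification needs all three inputs; a pixel missing any (masked CV,
  # short series, masked landcover) is nodata, not "not significant"
  has_data <- !is.na(pn) & !is.na(pc) & !is.na(mu)
  dual <- has_data & pn < alpha & pc < alpha
  sparse <- mu < ndvi_threshold
  lab <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  lab[has_data] <- "not_significant"
  idx <- which(dual)
  up_n <- sn[idx] > 0; up_c <- sc[idx] > 0; sp <- sparse[idx]
  cls <- rep("not_significant", length(idx))
  cls[up_n & !up_c] <- "improving"
  cls[up_n & up_c & sp] <- "regrowing"
  cls[up_n & up_c & !sp] <- "slight_degradation"
  cls[!up_n & up_c] <- "medium_degradation"
  cls[!up_n & !up_c & !sp] <- "severe_degradation"
  cls[!up_n & !up_c & sp] <- "desertification"
  lab[idx] <- cls
  structure(list(grid = grid, labels = lab), class = "change_class_raster")
}

#' @export
print.change_class_raster <- function(x, ...) {
  tab <- table(factor(x$labels, levels = change_class_levels()))
  cat(sprintf("<change_class_raster> %d x %d pixels\n",
              x$grid$n_rows, x$grid$n_cols))
  print(tab)
  invisible(x)
}

#' Area shares of the change classes, overall and by grassland type
#'
#' Counts pixels per class among the significantly changed area, for all
#' pixels and restricted to the steppe and meadow strata. `percent` is the
#' class share of the dual-significant area (the denominator the class
#' shares are reported on); `percent_of_valid` reports the same count
#' against all pixels carrying data, the denominator under which the
#' significant area itself is quoted as a share of the study region.
#'
#' @param classes A [classify_change()] raster.
#' @param grassland Character matrix over `{steppe, meadow, other}`
#'   conforming to the same grid, or `NULL` for no stratification.
#' @return A tibble with columns `stratum`, `class`, `count`, `area_km2`,
#'   `percent`, `percent_of_valid`.
#' @export
summarize_proportions <- function(classes, grassland = NULL) {
  stopifnot(inherits(classes, "change_class_raster"))
  grid <- classes$grid
  if (!is.null(grassland)) check_raster_conforms(grassland, grid, "grassland raster")
  px_km2 <- (grid$pixel_size / 1000)^2
  six <- setdiff(change_class_levels(), "not_significant")
  strata <- list(all = rep(TRUE, length(classes$labels)))
  if (!is.null(grassland)) {
    strata$steppe <- as.vector(grassland == "steppe")
    strata$meadow <- as.vector(grassland == "meadow")
  }
  lab <- as.vector(classes$labels)
  purrr::imap_dfr(strata, function(sel, nm) {
    l <- lab[sel & !is.na(lab)]
    n_valid <- length(l)
    n_sig <- sum(l != "not_significant")
    counts <- table(factor(l[l != "not_significant"], levels = six))
    tibble::tibble(
      stratum = nm, class = six, count = as.integer(counts),
      area_km2 = as.integer(counts) * px_km2,
      percent = if (n_sig > 0) 100 * as.integer(counts) / n_sig else 0,
      percent_of_valid = if (n_valid > 0) 100 * as.integer(counts) / n_valid else 0)
  })
}

#' Direction-of-change summary for driver trend surfaces
#'
#' For each driver, the share of valid pixels whose slope increases,
#' decreases, or is unchanged (|slope| within `epsilon`), plus the
#' significant sub-fractions at level `alpha`. With the default
#' `epsilon = 0`, "unchanged" means a literally zero slope, which occurs for
#' discrete-valued inputs such as population counts.
#'
#' @param driver_trends A list of [fit_linear_trend()] surfaces (typically
#'   named by driver).
#' @param epsilon Slope dead-band, scalar or named per variable, `>= 0`.
#' @param alpha Significance level for the significant sub-fractions.
#' @return A tibble with one row per variable: `variable`, `n_valid`,
#'   `increase`, `decrease`, `unchanged`, `significant_increase`,
#'   `significant_decrease` (percent of valid pixels).
#' @export
driver_trend_summary <- function(driver_trends, epsilon = 0, alpha = 0.05) {
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  purrr::map_dfr(driver_trends, function(tr) {
    stopifnot(inherits(tr, "trend_surface"))
    eps <- if (!is.null(names(epsilon)) && tr$variable %in% names(epsilon)) {
      epsilon[[tr$variable]]
    } else epsilon[1]
    s <- as.vector(tr$slope); p <- as.vector(tr$p_value)
    ok <- !is.na(s)
    s <- s[ok]; p <- p[ok]
    n <- length(s)
    pct <- function(x) if (n > 0) 100 * sum(x) / n else 0
    tibble::tibble(
      variable = tr$variable, n_valid = n,
      increase = pct(s > eps), decrease = pct(s < -eps),
      unchanged = pct(abs(s) <= eps),
      significant_increase = pct(s > eps & !is.na(p) & p < alpha),
      significant_decrease = pct(s < -eps & !is.na(p) & p < alpha))
  })
}
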