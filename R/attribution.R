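#' Per-pixel Pearson correlation between a response and a driver
#'
#' Correlates the annual response series (NDVI composite or focal CV) with
#' one annual driver series pixel by pixel over their common valid years,
#' with a two-sided t-test (n-2 degrees of freedom) on the coefficient.
#' Pixels with fewer than `min_years` common years, or with a zero-variance
#' series on either side, get nodata rather than an error.
#'
#' @param response An [annual_stack()].
#' @param driver A numeric array with the same dimensions (one
#'   [driver_stack()] variable), or an [annual_stack()] on the same years.
#' @param min_years Minimum common valid years (default 3).
#' @return A list with matrices `r` and `p_value` and the `grid`.
#' @export
pixelwise_pearson <- function(response, driver, min_years = 3) {
  stopifnot(inherits(response, "annual_stack"))
  if (inherits(driver, "annual_stack")) {
    if (!identical(driver$years, response$years)) {
      stop("response and driver stacks cover different years", call. = FALSE)
    }
    driver <- driver$values
  }
  stopifnot(identical(dim(driver), dim(response$values)))
  grid <- response$grid
  np <- grid$n_rows * grid$n_cols
  ny <- length(response$years)
  X <- matrix(response$values, np, ny)
  Y <- matrix(driver, np, ny)
  M <- !is.na(X) & !is.na(Y)
  X0 <- ifelse(M, X, 0); Y0 <- ifelse(M, Y, 0)
  n <- rowSums(M)
  sx <- rowSums(X0); sy <- rowSums(Y0)
  sxx <- rowSums(X0^2); syy <- rowSums(Y0^2); sxy <- rowSums(X0 * Y0)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  r <- cxy / sqrt(vx * vy)
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[is.infinite(tstat)] <- 0      # |r| = 1 exactly
  bad <- n < max(3, min_years) | vx <= 0 | vy <= 0
  r[bad] <- NA_real_; p[bad] <- NA_real_
  list(grid = grid, r = matrix(r, grid$n_rows, grid$n_cols),
       p_value = matrix(p, grid$n_rows, grid$n_cols))
}

#' Area shares of significant correlations for every response x driver pair
#'
#' For each response (NDVI, CV) and each of the six drivers: the percent of
#' valid pixels whose correlation is significant at `alpha`, and among those,
#' the percent positive and percent negative (these two always sum to 100
#' when any pixel is significant).
#'
#' @param responses Named list of [annual_stack()]s, conventionally
#'   `list(NDVI = ..., CV = ...)`.
#' @param drivers A [driver_stack()] on the same grid and years.
#' @param alpha Significance level (default 0.05).
#' @param min_years Passed to [pixelwise_pearson()].
#' @return A tibble with columns `response`, `variable`, `n_valid`,
#'   `percent_significant`, `percent_positive_among_significant`,
#'   `percent_negative_among_significant`.
#' @export
summarize_correlations <- function(responses, drivers, alpha = 0.05,
                                   min_years = 3) {
  stopifnot(inherits(drivers, "driver_stack"), is.list(responses))
  purrr::imap_dfr(responses, function(resp, rname) {
    stop_if_grid_mismatch(resp$grid, drivers$grid, "response and drivers")
    purrr::imap_dfr(drivers$variables, function(drv, vname) {
      pr <- pixelwise_pearson(resp, drv, min_years = min_years)
      ok <- !is.na(pr$r) & !is.na(pr$p_value)
      n_valid <- sum(ok)
      sig <- ok & pr$p_value < alpha
      n_sig <- sum(sig)
      tibble::tibble(
        response = rname, variable = vname, n_valid = n_valid,
        percent_significant = if (n_valid > 0) 100 * n_sig / n_valid else 0,
        percent_positive_among_significant =
          if (n_sig > 0) 100 * sum(pr$r[sig] > 0) / n_sig else NA_real_,
        percent_negative_among_significant =
          if (n_sig > 0) 100 * sum(pr$r[sig] < 0) / n_sig else NA_real_)
    })
  })
}

#' Extract stratified pixel-year samples for driver attribution
#'
#' The observation unit is the pixel-year. Pixels carrying one of the six
#' change classes are crossed with the grassland type (steppe, meadow) into
#' up to twelve strata; rows with any missing response or driver value are
#' dropped, then any stratum larger than `sample_cap` is subsampled
#' uniformly without replacement with the given seed (a stratum at or below
#' the cap keeps every row). Empty strata are omitted with a warning.
#'
#' @param classes A [classify_change()] raster.
#' @param grassland Character matrix over `{steppe, meadow, other}`.
#' @param responses Named list of [annual_stack()]s, conventionally
#'   `list(NDVI = ..., CV = ...)`; values become `response_<name>` columns.
#' @param drivers A [driver_stack()] on the same grid and years.
#' @param sample_cap Per-stratum cap (default 10000).
#' @param seed Integer seed for the subsampling.
#' @param unit `"pixel_year"` (default) or `"pixel"`; the latter averages
#'   each pixel's series over years first.
#' @return A tibble with columns `pixel_id`, `year`, `stratum`, `grassland`,
#'   `class`, the response columns and the six drivers.
#' @export
extract_strata_samples <- function(classes, grassland, responses, drivers,
                                   sample_cap = 10000, seed = 1,
                                   unit = c("pixel_year", "pixel")) {
  unit <- match.arg(unit)
  stopifnot(inherits(classes, "change_class_raster"),
            inherits(drivers, "driver_stack"), sample_cap >= 1)
  grid <- classes$grid
  check_raster_conforms(grassland, grid, "grassland raster")
  for (r in responses) stop_if_grid_mismatch(r$grid, grid, "responses")
  years <- drivers$years
  lab <- as.vector(classes$labels)
  gl <- as.vector(grassland)
  keep_px <- which(!is.na(lab) & lab != "not_significant" &
                     gl %in% c("steppe", "meadow"))
  if (length(keep_px) == 0) {
    warning("no dual-significant steppe/meadow pixels; empty sample table")
    return(tibble::tibble())
  }
  np <- grid$n_rows * grid$n_cols
  ny <- length(years)
  pull_years <- function(arr) matrix(arr, np, ny)[keep_px, , drop = FALSE]
  tab <- tibble::tibble(
    pixel_id = rep(keep_px, times = ny),
    year = rep(years, each = length(keep_px)),
    grassland = rep(gl[keep_px], times = ny),
    class = rep(lab[keep_px], times = ny))
  for (nm in names(responses)) {
    stopifnot(identical(responses[[nm]]$years, years))
    tab[[paste0("response_", tolower(nm))]] <- as.vector(pull_years(responses[[nm]]$values))
  }
  for (v in names(drivers$variables)) {
    tab[[v]] <- as.vector(pull_years(drivers$variables[[v]]))
  }
  tab$stratum <- paste(tab$grassland, tab$class, sep = ".")
  tab <- tidyr::drop_na(tab)
  if (unit == "pixel") {
    tab <- tab |>
      dplyr::group_by(.data$pixel_id, .data$stratum, .data$grassland, .data$class) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric) & !dplyr::matches("^year$"),
                                     mean), .groups = "drop") |>
      dplyr::select(-dplyr::any_of("year"))
  }
  expected <- length(unique(paste(gl[keep_px], lab[keep_px])))
  got <- length(unique(tab$stratum))
  if (got < expected) {
    warning(sprintf("%d stratum(s) empty after dropping incomplete rows",
                    expected - got))
  }
  withr::with_seed(seed, {
    tab <- tab |>
      dplyr::group_by(.data$stratum) |>
      dplyr::slice_sample(n = sample_cap) |>
      dplyr::ungroup()
  })
  dplyr::relocate(tab, "pixel_id", "stratum", "grassland", "class")
}

#' Random-forest driver importance per stratum
#'
#' For every stratum in the sample table: the number of trees is selected
#' from `tree_grid` by k-fold cross-validated mean squared error (each fold
#' fits `max(tree_grid)` trees once and scores truncated forests from the
#' cumulative per-tree predictions), then a final forest of the response on
#' the six drivers is fitted. Feature importance is the mean decrease in
#' impurity, normalised to sum to one per stratum; model fit is the
#' out-of-bag R-squared. Strata smaller than `min_stratum_n` or with a
#' constant response are skipped with a warning.
#'
#' @param samples An [extract_strata_samples()] tibble.
#' @param response `"ndvi"` or `"cv"` (selects `response_ndvi` /
#'   `response_cv`).
#' @param tree_grid Candidate tree counts (default
#'   `c(100, 200, 300, 500, 800)`).
#' @param cv_folds Cross-validation folds for the tree count (default 5).
#' @param seed Integer seed controlling folds and forests.
#' @param min_stratum_n Minimum rows per stratum (default 50).
#' @return A tibble of class `importance_table`: one row per
#'   (stratum, factor) with `response`, `importance`, and per-stratum
#'   `r_squared`, `n_samples`, `n_trees` repeated on each row.
#' @export
fit_importance <- function(samples, response = c("ndvi", "cv"),
                           tree_grid = c(100, 200, 300, 500, 800),
                           cv_folds = 5, seed = 1, min_stratum_n = 50) {
  response <- match.arg(response)
  ycol <- paste0("response_", response)
  stopifnot(ycol %in% names(samples))
  preds <- intersect(driver_names(), names(samples))
  if (length(preds) < 6) stop("all six driver predictors must be present",
                              call. = FALSE)
  out <- list()
  for (st in sort(unique(samples$stratum))) {
    rows <- samples[samples$stratum == st, , drop = FALSE]
    if (nrow(rows) < min_stratum_n) {
      warning(sprintf("stratum '%s' has %d < %d rows; skipped",
                      st, nrow(rows), min_stratum_n))
      next
    }
    y <- rows[[ycol]]
    if (stats::sd(y) == 0) {
      warning(sprintf("stratum '%s' has a constant response; skipped", st))
      next
    }
    X <- as.data.frame(rows[preds])
    fit <- withr::with_seed(seed, {
      nt <- select_n_trees(X, y, tree_grid, cv_folds)
      f <- randomForest::randomForest(x = X, y = y, ntree = nt)
      list(forest = f, n_trees = nt)
    })
    imp <- randomForest::importance(fit$forest, type = 2)[, 1]
    imp <- imp[preds] / sum(imp)
    r2 <- fit$forest$rsq[fit$n_trees]
    out[[st]] <- tibble::tibble(
      response = response, stratum = st, factor = preds,
      importance = as.numeric(imp), r_squared = r2,
      n_samples = nrow(rows), n_trees = fit$n_trees)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("importance_table", class(res))
  res
}

# Pick the tree count with the lowest cv-fold mean squared error; scores all
# candidates from one max-size forest per fold via cumulative per-tree means.
select_n_trees <- function(X, y, tree_grid, cv_folds) {
  tree_grid <- sort(unique(as.integer(tree_grid)))
  if (length(tree_grid) == 1) return(tree_grid)
  n <- length(y)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  mse <- matrix(NA_real_, cv_folds, length(tree_grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                      ntree = max(tree_grid))
    ind <- stats::predict(fit, X[!tr, , drop = FALSE], predict.all = TRUE)$individual
    cums <- t(apply(ind, 1, cumsum))
    for (j in seq_along(tree_grid)) {
      pred <- cums[, tree_grid[j]] / tree_grid[j]
      mse[f, j] <- mean((pred - y[!tr])^2)
    }
  }
  tree_grid[which.min(colMeans(mse))]
}

#' Aggregate factor importances into climate and human shares
#'
#' Climate share is the summed importance of Pre, Temp, RH and SPEI; human
#' share sums Graz and Pop. Shares are percentages summing to 100 per
#' (response, stratum), and an `average` row per response gives the mean
#' over its strata.
#'
#' @param importances A [fit_importance()] table (responses may be mixed).
#' @return A tibble with columns `response`, `stratum`, `climate_share`,
#'   `human_share`.
#' @export
aggregate_contributions <- function(importances) {
  climate <- c("Pre", "Temp", "RH", "SPEI")
  per <- importances |>
    dplyr::group_by(.data$response, .data$stratum) |>
    dplyr::summarise(
      climate_share = 100 * sum(.data$importance[.data$factor %in% climate]),
      human_share = 100 * sum(.data$importance[!.data$factor %in% climate]),
      .groups = "drop")
  avg <- per |>
    dplyr::group_by(.data$response) |>
    dplyr::summarise(stratum = "average",
                     climate_share = mean(.data$climate_share),
                     human_share = mean(.data$human_share), .groups = "drop")
  dplyr::bind_rows(per, avg)
}
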