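#' Annual growing-season median NDVI composite
#'
#' Collapses a monthly NDVI stack to one value per pixel-year: the median of
#' the valid growing-season months (May-September by default). A pixel-year
#' with fewer than `min_valid_months` valid observations gets nodata, which
#' keeps noisy, cloud-gap-like series out of the trend fits.
#'
#' @param stack A [monthly_stack()].
#' @param months Integer set of growing-season months, default `5:9`.
#' @param min_valid_months Minimum valid months per pixel-year (default 3).
#' @return An [annual_stack()] of composites.
#' @export
growing_season_median <- function(stack, months = 5:9, min_valid_months = 3) {
  stopifnot(inherits(stack, "monthly_stack"))
  if (!all(months %in% 1:12)) stop("months must lie in 1..12", call. = FALSE)
  sel <- stack$index$month %in% months
  if (!any(sel)) stop("no stack layers fall in the requested months", call. = FALSE)
  years <- sort(unique(stack$index$year[sel]))
  grid <- stack$grid
  out <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, length(years)))
  for (i in seq_along(years)) {
    k <- which(sel & stack$index$year == years[i])
    slab <- stack$values[, , k, drop = FALSE]
    n_valid <- rowSums(!is.na(slab), dims = 2)
    med <- apply(slab, c(1, 2), stats::median, na.rm = TRUE)
    med[n_valid < min_valid_months] <- NA_real_
    out[, , i] <- med
  }
  annual_stack(grid, years, out)
}

#' Focal coefficient of variation of an annual composite
#'
#' Spatial heterogeneity surface: for every pixel and year, the coefficient
#' of variation CV = s/m of the 3 x 3 window of composite values centred on
#' the pixel, where m is the window mean and s the sample standard deviation
#' (divisor n-1; the 9 window values are a sample of the local surface).
#' The window must be complete: any masked or nodata member, a masked
#' center, a window leaving the grid, or a window mean at or below
#' `mean_floor` all yield nodata. High CV marks patchy vegetation/bare-soil
#' mosaics; its trend over years is the degradation signal the change
#' classification consumes.
#'
#' @param composite An [annual_stack()] of NDVI composites.
#' @param window Odd window size `>= 3` (default 3).
#' @param mask Optional [build_mask_set()] result; masked pixels are removed
#'   before windowing.
#' @param mean_floor Windows whose mean is `<= mean_floor` are nodata to
#'   avoid division blow-ups near zero-mean windows (default `1e-6`).
#' @return An [annual_stack()] of CV values.
#' @export
focal_cv <- function(composite, window = 3, mask = NULL, mean_floor = 1e-6) {
  stopifnot(inherits(composite, "annual_stack"))
  if (window %% 2 == 0 || window < 3) {
    stop("window size must be odd and >= 3", call. = FALSE)
  }
  grid <- composite$grid
  h <- (window - 1L) / 2L
  n_win <- window^2
  out <- array(NA_real_, dim = dim(composite$values))
  mask_m <- if (is.null(mask)) NULL else mask$combined
  for (k in seq_along(composite$years)) {
    v <- composite$values[, , k]
    if (!is.null(mask_m)) v[mask_m] <- NA_real_
    valid <- !is.na(v)
    v0 <- ifelse(valid, v, 0)
    s1 <- shift_sum(v0, h); s2 <- shift_sum(v0^2, h)
    cnt <- shift_sum(valid * 1, h)
    m <- s1 / n_win
    var_s <- (s2 - s1^2 / n_win) / (n_win - 1)
    var_s[var_s < 0] <- 0  # guard float cancellation
    cv <- sqrt(var_s) / m
    cv[cnt < n_win] <- NA_real_       # incomplete window
    cv[!valid] <- NA_real_            # masked/nodata center
    cv[m <= mean_floor] <- NA_real_   # near-zero or negative window mean
    out[, , k] <- cv
  }
  annual_stack(grid, composite$years, out)
}

# Sum over the (2h+1)^2 window by shifting; borders -> NA.
shift_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in -h:h) {
    rs <- seq_len(nr) + dr
    ok_r <- rs >= 1 & rs <= nr
    for (dc in -h:h) {
      cs <- seq_len(nc) + dc
      ok_c <- cs >= 1 & cs <= nc
      shifted <- matrix(NA_real_, nr, nc)
      shifted[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
      acc <- acc + shifted
    }
  }
  acc
}

#' Multi-year mean NDVI surface
#'
#' Arithmetic mean of the annual composites per pixel, used as the sparse
#' vegetation threshold surface (mean NDVI below 0.2 marks desert or
#' sparsely vegetated ground). Pixels with fewer than `min_valid_years`
#' valid years get nodata.
#'
#' @param composite An [annual_stack()].
#' @param min_valid_years Minimum valid years per pixel (default 15).
#' @return An object of class `mean_ndvi_surface` with fields `grid` and
#'   `values` (matrix).
#' @export
period_mean <- function(composite, min_valid_years = 15) {
  stopifnot(inherits(composite, "annual_stack"))
  if (length(composite$years) == 0) stop("empty stack", call. = FALSE)
  n_valid <- rowSums(!is.na(composite$values), dims = 2)
  v0 <- composite$values
  v0[is.na(v0)] <- 0
  m <- rowSums(v0, dims = 2) / n_valid
  m[n_valid < min_valid_years] <- NA_real_
  structure(list(grid = composite$grid, values = m),
            class = "mean_ndvi_surface")
}
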