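#' Define a raster analysis grid
#'
#' A `raster_grid` fixes the geometry every raster in an analysis must share:
#' dimensions, top-left corner, square pixel size, a CRS identifier and the
#' nodata sentinel used in files. Row 1 is the top row; pixel coordinates
#' refer to cell centers. Grid equality is exact field-by-field equality, so
#' rasters can only be combined when they were produced on literally the same
#' grid.
#'
#' @param n_rows,n_cols Integer raster dimensions.
#' @param origin_x,origin_y Map coordinates of the top-left corner of the
#'   top-left pixel (not its center), in map units.
#' @param pixel_size Side length of the square pixels, map units (default
#'   250, the MODIS-style resolution this analysis is designed around).
#' @param crs_id Free-text CRS identifier; inputs must share one CRS, no
#'   reprojection is performed.
#' @param nodata Sentinel value written to / read from files for missing
#'   pixels. In memory missing pixels are always `NA`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(n_rows, n_cols, origin_x = 0, origin_y = NULL,
                        pixel_size = 250, crs_id = "local", nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0)
  if (is.null(origin_y)) origin_y <- n_rows * pixel_size
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size), crs_id = as.character(crs_id),
         nodata = as.numeric(nodata)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d pixels, size %g, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Test two grids for exact equality
#'
#' @param a,b `raster_grid` objects.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b) {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b)) {
    stop(sprintf("grid mismatch: %s must share one analysis grid", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Map-unit coordinates of pixel centers
#'
#' @param grid A `raster_grid`.
#' @return A list with numeric vectors `x` (length `n_cols`, left to right)
#'   and `y` (length `n_rows`, top to bottom).
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size,
       y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$pixel_size)
}

check_raster_conforms <- function(values, grid, what = "raster") {
  if (!is.matrix(values) || nrow(values) != grid$n_rows ||
      ncol(values) != grid$n_cols) {
    stop(sprintf("%s does not conform to the grid (%d x %d expected)",
                 what, grid$n_rows, grid$n_cols), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a single raster layer to a tidy tibble
#'
#' Bridges matrix-backed rasters into the tidyverse: one row per pixel with
#' grid indices, center coordinates and the value.
#'
#' @param values Numeric or character matrix conforming to `grid`.
#' @param grid A `raster_grid`.
#' @param name Column name for the value (default `"value"`).
#' @return A tibble with columns `row`, `col`, `x`, `y` and `name`.
#' @export
raster_to_tibble <- function(values, grid, name = "value") {
  check_raster_conforms(values, grid)
  ctr <- pixel_centers(grid)
  out <- tibble::tibble(
    row = rep(seq_len(grid$n_rows), times = grid$n_cols),
    col = rep(seq_len(grid$n_cols), each = grid$n_rows),
    x = rep(ctr$x, each = grid$n_rows),
    y = rep(ctr$y, times = grid$n_cols),
    value = as.vector(values))
  names(out)[names(out) == "value"] <- name
  out
}
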