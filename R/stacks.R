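#' Monthly NDVI raster stack
#'
#' Container for a multi-year monthly NDVI time series on one grid. Values
#' are unitless NDVI in `[-1, 1]`; missing pixels are `NA`. The layer index
#' is an ordered `(year, month)` table and must be strictly increasing in
#' calendar time.
#'
#' @param grid A [raster_grid()].
#' @param index A data frame with integer columns `year` and `month`, one row
#'   per layer, strictly increasing in calendar order.
#' @param values A numeric array `n_rows x n_cols x n_layers`.
#' @return An object of class `monthly_stack`.
#' @export
monthly_stack <- function(grid, index, values) {
  stopifnot(inherits(grid, "raster_grid"))
  index <- tibble::as_tibble(index)
  stopifnot(all(c("year", "month") %in% names(index)))
  index$year <- as.integer(index$year)
  index$month <- as.integer(index$month)
  if (nrow(index) == 0) stop("empty stack: index has no layers", call. = FALSE)
  if (!all(index$month %in% 1:12)) stop("months must lie in 1..12", call. = FALSE)
  key <- index$year * 12 + index$month
  if (any(diff(key) <= 0)) {
    stop("stack index must be strictly increasing in (year, month)", call. = FALSE)
  }
  values <- check_stack_values(values, grid, nrow(index))
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1 || rng[2] > 1)) {
    stop("NDVI values must lie in [-1, 1] or be NA", call. = FALSE)
  }
  structure(list(grid = grid, index = index, values = values),
            class = "monthly_stack")
}

check_stack_values <- function(values, grid, n_layers) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("stack values must be a 3-d array [rows, cols, layers]", call. = FALSE)
  }
  d <- dim(values)
  if (d[1] != grid$n_rows || d[2] != grid$n_cols || d[3] != n_layers) {
    stop(sprintf("stack values must be %d x %d x %d",
                 grid$n_rows, grid$n_cols, n_layers), call. = FALSE)
  }
  values
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat(sprintf("<monthly_stack> %d layers (%d-%02d .. %d-%02d), %d x %d pixels\n",
              nrow(x$index), x$index$year[1], x$index$month[1],
              x$index$year[nrow(x$index)], x$index$month[nrow(x$index)],
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Annual raster stack
#'
#' One raster layer per year on a common grid: growing-season NDVI composites,
#' focal-CV heterogeneity surfaces or annual driver fields all live in this
#' container.
#'
#' @param grid A [raster_grid()].
#' @param years Strictly increasing integer vector of years.
#' @param values Numeric array `n_rows x n_cols x n_years`.
#' @return An object of class `annual_stack`.
#' @export
annual_stack <- function(grid, years, values) {
  stopifnot(inherits(grid, "raster_grid"))
  years <- as.integer(years)
  if (length(years) == 0) stop("empty stack: no years", call. = FALSE)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)
  values <- check_stack_values(values, grid, length(years))
  structure(list(grid = grid, years = years, values = values),
            class = "annual_stack")
}

#' @export
print.annual_stack <- function(x, ...) {
  cat(sprintf("<annual_stack> years %d..%d (%d), %d x %d pixels\n",
              min(x$years), max(x$years), length(x$years),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Annual driver stack
#'
#' Six annual driver variables on one grid and one set of years:
#' precipitation `Pre` (mm), mean temperature `Temp` (degrees C), relative
#' humidity `RH` (%), drought index `SPEI` (unitless), grazing intensity
#' `Graz` (livestock density units) and population density `Pop` (persons per
#' cell).
#'
#' @param grid A [raster_grid()].
#' @param years Strictly increasing integer vector.
#' @param variables Named list of numeric arrays `n_rows x n_cols x n_years`;
#'   names must be a subset of the six canonical driver names.
#' @return An object of class `driver_stack`.
#' @export
driver_stack <- function(grid, years, variables) {
  stopifnot(inherits(grid, "raster_grid"), is.list(variables))
  years <- as.integer(years)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)
  bad <- setdiff(names(variables), driver_names())
  if (length(bad) > 0) {
    stop("unknown driver variable name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  variables <- lapply(variables, check_stack_values, grid = grid,
                      n_layers = length(years))
  structure(list(grid = grid, years = years, variables = variables),
            class = "driver_stack")
}

#' Canonical driver variable names
#' @return Character vector of the six driver names.
#' @export
driver_names <- function() c("Pre", "Temp", "RH", "SPEI", "Graz", "Pop")

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack> %s; years %d..%d, %d x %d pixels\n",
              paste(names(x$variables), collapse = ", "),
              min(x$years), max(x$years), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' @describeIn raster_to_tibble Long tibble of an annual stack (one row per
#'   pixel-year).
#' @param x An `annual_stack`.
#' @param ... Unused.
#' @method as_tibble annual_stack
#' @export
as_tibble.annual_stack <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$years), x$years, function(k, yr) {
    dplyr::mutate(raster_to_tibble(x$values[, , k], x$grid), year = yr,
                  .before = 1)
  })
}
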