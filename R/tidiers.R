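#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-stratum importance table
#'
#' One row per (response, stratum, factor) with the normalised importance.
#'
#' @param x A [fit_importance()] table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy importance_table
#' @export
tidy.importance_table <- function(x, ...) {
  tibble::as_tibble(x[c("response", "stratum", "factor", "importance")])
}

#' One-row-per-model summary of importance fits
#'
#' @param x A [fit_importance()] table.
#' @param ... Unused.
#' @return A tibble with `response`, `stratum`, `r_squared`, `n_samples`,
#'   `n_trees`.
#' @method glance importance_table
#' @export
glance.importance_table <- function(x, ...) {
  dplyr::distinct(tibble::as_tibble(
    x[c("response", "stratum", "r_squared", "n_samples", "n_trees")]))
}

#' @method tidy trend_surface
#' @export
tidy.trend_surface <- function(x, ...) {
  df <- raster_to_tibble(x$slope, x$grid, name = "slope")
  df$p_value <- as.vector(x$p_value)
  df$n_years <- as.vector(x$n_years)
  df$variable <- x$variable
  df
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL
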