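#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a change-class raster
#'
#' @param object A [classify_change()] raster.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot change_class_raster
#' @export
autoplot.change_class_raster <- function(object, ...) {
  df <- raster_to_tibble(object$labels, object$grid, name = "class")
  df$class <- factor(df$class, levels = change_class_levels())
  pal <- c(improving = "#1a9850", regrowing = "#91cf60",
           slight_degradation = "#fee08b", medium_degradation = "#fc8d59",
           severe_degradation = "#d73027", desertification = "#7f3b08",
           not_significant = "grey85")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, na.value = "white",
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "change class") +
    ggplot2::theme_minimal()
}

#' Plot a trend surface (slope map with significance hatching removed)
#'
#' @param object A [fit_linear_trend()] surface.
#' @param what `"slope"` or `"p_value"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trend_surface
#' @export
autoplot.trend_surface <- function(object, what = c("slope", "p_value"), ...) {
  what <- match.arg(what)
  df <- raster_to_tibble(object[[what]], object$grid, name = what)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s %s", object$variable, what),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of class proportions by stratum
#'
#' @param proportions A [summarize_proportions()] tibble.
#' @return A ggplot.
#' @export
plot_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$class, y = .data$percent,
                               fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of significantly changed area") +
    ggplot2::theme_minimal()
}

#' Plot factor importances per stratum
#'
#' @param object A [fit_importance()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot importance_table
#' @export
autoplot.importance_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$factor, y = .data$importance,
                               fill = .data$factor)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(response ~ stratum) +
    ggplot2::labs(x = NULL, y = "normalised importance (mean decrease in impurity)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
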