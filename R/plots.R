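#' Map a grid-stack time slice or time mean
#'
#' @param object A grid stack.
#' @param date Optional single date to plot; default plots the per-pixel
#'   time mean.
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.grid_stack <- function(object, date = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(date)) {
    df <- df[df$date == as.Date(date), ]
    ttl <- format(as.Date(date))
  } else {
    df <- df |>
      dplyr::group_by(.data$row, .data$col) |>
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    ttl <- "time mean"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = stack_units(object)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = ttl, x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Map the five-class trend categories
#'
#' @param object An `agb_trend` tibble from [trend_analysis()].
#' @param ... Unused.
#' @return A ggplot raster map with a diverging category palette.
#' @export
autoplot.agb_trend <- function(object, ...) {
  pal <- c("significant degradation" = "#b2182b",
           "slight degradation" = "#ef8a62",
           "stable" = "#f7f7f7",
           "slight improvement" = "#67a9cf",
           "significant improvement" = "#2166ac")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE, name = "trend") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Map the five stability levels
#'
#' @param object An `agb_stability` tibble from [stability_analysis()].
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.agb_stability <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", drop = FALSE,
                               name = "fluctuation") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Bar chart of random-forest driver importance shares
#'
#' @param x An `rf_importance` object.
#' @return A ggplot bar chart, drivers ordered by share.
#' @export
plot_importance <- function(x) {
  imp <- tidy(x)
  imp$driver <- factor(imp$driver, levels = rev(imp$driver))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$share, y = .data$driver)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "relative importance (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
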