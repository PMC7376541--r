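#' Plot a simulated trajectory
#'
#' Lines of each concentration over time, faceted by component, coloured by
#' cell.
#'
#' @param object An `nd_trajectory`.
#' @param cells Optional subset of cell indices to draw.
#' @param components Components to draw (default all of `D`, `N`, `A`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nd_trajectory <- function(object, cells = NULL,
                                   components = c("D", "N", "A"), ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(cells)) df <- df[df$cell %in% cells, ]
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(components),
                              names_to = "component", values_to = "concentration")
  long$component <- factor(long$component, levels = c("D", "N", "A"),
                           labels = c("Delta", "Notch", "activated Notch"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$concentration,
                                     colour = factor(.data$cell))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time", y = "concentration", colour = "cell") +
    ggplot2::theme_minimal()
}

#' Plot a lattice phenotype as a blue-intensity heatmap
#'
#' Tile heatmap of the terminal Notch matrix, blue intensity proportional to
#' the normalised Notch level (the convention of the intestine stainings);
#' row 1 is drawn at the top.
#'
#' @param object An `nd_phenotype`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nd_phenotype <- function(object, ...) {
  notch <- attr(object, "notch")
  df <- expand.grid(row = seq_len(nrow(notch)), col = seq_len(ncol(notch)))
  df$notch <- as.vector(notch)
  mx <- max(notch)
  df$intensity <- if (mx > 0) df$notch / mx else 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306B",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(notch))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = "row", fill = "Notch",
                  title = paste("phenotype:", attr(object, "phenotype"))) +
    ggplot2::theme_minimal()
}

#' Plot Morris sensitivities
#'
#' Bar chart of the mean absolute elementary effects, ordered by rank.
#'
#' @param object An `nd_morris`.
#' @param log_scale Draw the sensitivity axis on a log10 scale (default
#'   `TRUE`; the effects typically span many orders of magnitude).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nd_morris <- function(object, log_scale = TRUE, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- stats::reorder(df$parameter, -df$sensitivity)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                         y = .data$sensitivity)) +
    ggplot2::geom_col(fill = "#2171B5") +
    ggplot2::labs(x = NULL, y = "mean |elementary effect|") +
    ggplot2::theme_minimal()
  if (log_scale) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Overlay plot of a parameter sweep
#'
#' @param sweep Output of [perturbation_sweep()].
#' @param component Which component to draw (default `"N"`).
#' @param cell Which cell to draw (default 1).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, component = "N", cell = 1) {
  df <- sweep[sweep$cell == cell, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[component]],
                                   colour = factor(.data$value))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = unique(df$parameter)[1], y = component) +
    ggplot2::theme_minimal()
}
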