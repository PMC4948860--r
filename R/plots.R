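#' Plot a shift table
#'
#' Per-island standardized diversity shifts, faceted by transition and
#' metric, with the zero line and significant islands highlighted.
#'
#' @param object a `shift_table` from [transition_table()].
#' @param alpha significance level used for highlighting.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.shift_table <- function(object, alpha = 0.05, ...) {
  d <- dplyr::mutate(object,
                     significant = .data$p <= alpha,
                     island_id = factor(.data$island_id,
                                        levels = unique(.data$island_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$island_id, y = .data$z,
                                  colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_grid(metric ~ transition) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#C0392B")) +
    ggplot2::labs(x = NULL, y = expression(Z[D]),
                  colour = paste0("p ≤ ", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot the apparent R-squared sequence of a regression tree
#'
#' @param object a `shift_tree` from [fit_tree()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.shift_tree <- function(object, ...) {
  d <- object$cp_table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_splits, y = .data$approx_r2)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$n_splits) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "number of splits", y = "apparent R²") +
    ggplot2::theme_minimal()
}

#' @export
plot.shift_table <- function(x, ...) print(autoplot.shift_table(x, ...))

#' @export
plot.shift_tree <- function(x, ...) print(autoplot.shift_tree(x, ...))
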