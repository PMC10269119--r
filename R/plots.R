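#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a diel activity density
#'
#' @param object A `diel_density` from [density_vonmises()].
#' @param ... Unused.
#' @return A ggplot: kernel density over the 24-h cycle.
#' @export
autoplot.diel_density <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$hour <- df$angle * 24 / (2 * pi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "Hour of day", y = "Activity density",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a pair of diel densities with their overlap region
#'
#' The shaded area under the pointwise minimum is the overlap coefficient.
#'
#' @param grid A [density_grid()] tibble.
#' @return A ggplot.
#' @export
plot_density_pair <- function(grid) {
  long <- tidyr::pivot_longer(grid, c("density_a", "density_b"),
                              names_to = "which", values_to = "density")
  long$label <- ifelse(long$which == "density_a", long$label_a, long$label_b)
  ggplot2::ggplot() +
    ggplot2::geom_area(data = grid,
                       ggplot2::aes(x = .data$hour, y = .data$minimum),
                       fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(x = .data$hour, y = .data$density,
                                    colour = .data$label), linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "Hour of day", y = "Activity density", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot derived occupancy estimates of a fitted model
#'
#' @param object An `msom_fit`.
#' @param ... Passed to [occupancy_estimates()].
#' @return A ggplot of estimates with confidence intervals, faceted by
#'   quantity type.
#' @export
autoplot.msom_fit <- function(object, ...) {
  est <- occupancy_estimates(object, ...)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$guilds, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a spatiotemporal overlap summary
#'
#' @param object An `overlap_summary` from [bootstrap_spatiotemporal()].
#' @param ... Unused.
#' @return A ggplot of proportions with bootstrap intervals.
#' @export
autoplot.overlap_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$guilds, y = .data$proportion,
                                   fill = .data$statistic)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Proportion of active grid-hour cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}
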