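#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of the log-CV mixture
#'
#' Histogram of the day-level log CV values with the two fitted component
#' densities and their sum overlaid.
#'
#' @param object A `cv_mixture` fit.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_mixture <- function(object, bins = 40, ...) {
  x <- object$values
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- tibble::tibble(
    log_cv = rep(grid, 3),
    density = c(object$weights[1] * stats::dnorm(grid, object$means[1],
                                                 object$sds[1]),
                object$weights[2] * stats::dnorm(grid, object$means[2],
                                                 object$sds[2]),
                object$weights[1] * stats::dnorm(grid, object$means[1],
                                                 object$sds[1]) +
                  object$weights[2] * stats::dnorm(grid, object$means[2],
                                                   object$sds[2])),
    component = rep(c("low CV", "high CV", "mixture"), each = length(grid)))
  ggplot2::ggplot(tibble::tibble(log_cv = x),
                  ggplot2::aes(x = .data$log_cv)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component,
                                    linetype = .data$component)) +
    ggplot2::labs(x = "log CV of daily feed intake (per batch-day)",
                  y = "density", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a gradient trajectory
#'
#' @param object A trajectory tibble from [total_genetic_variance()],
#'   [correlation_dfi_trait()] or [correlation_total_slope()] (rows of
#'   several calls may be combined with `dplyr::bind_rows()`).
#' @param ... Unused.
#' @return A ggplot faceted by quantity.
#' @export
autoplot.rn_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c6e91") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "environmental gradient p (challenge probability)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Figure-style gradient panel for one trait pair
#'
#' Two-panel display of the total genetic variance of DFI and the
#' correlation between total breeding value and slope along the gradient,
#' with the insensitivity point marked.
#'
#' @inheritParams total_genetic_variance
#' @return A ggplot.
#' @export
plot_gradient_summary <- function(K, p_grid = seq(0, 1, length.out = 101)) {
  gs <- gradient_summary(K, p_grid)
  dat <- gs$trajectories[gs$trajectories$quantity != "correlation_dfi_trait", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c6e91") +
    ggplot2::geom_vline(xintercept = gs$p_star, colour = "red",
                        linetype = "dotted") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "environmental gradient p (challenge probability)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
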