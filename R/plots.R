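#' @rdname simulate_population
#' @method autoplot popsim_trajectory
#' @export
autoplot.popsim_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generations,
                                   y = .data$mean_rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rate - .data$sd_rate,
                                      ymax = .data$mean_rate + .data$sd_rate),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = "generations (population doublings)",
                  y = "population mean growth rate",
                  title = sprintf("%s inheritance, %d founders",
                                  attr(object, "config")$inheritance,
                                  attr(object, "config")$n_founders)) +
    ggplot2::theme_minimal()
}

#' Overlay standardized snapshot distributions
#'
#' Visualizes the scaling collapse: each snapshot's values are standardized
#' and drawn as a density; a one-shape family superimposes onto a single
#' curve.
#'
#' @inheritParams standardize_snapshots
#' @return A ggplot object.
#' @export
plot_collapse <- function(data, value = "value", group = "snapshot") {
  std <- standardize_snapshots(data, value, group)
  ggplot2::ggplot(std, ggplot2::aes(x = .data$standardized,
                                    colour = factor(.data[[group]]))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "(value - mean) / sd", y = "density",
                  colour = "snapshot") +
    ggplot2::theme_minimal()
}
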