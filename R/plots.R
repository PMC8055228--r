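#' Plot an experiment's regret curve
#'
#' Median relative balanced-accuracy regret per iteration with its bootstrap
#' 95% confidence band. Lower is better; a learning strategy's curve should
#' fall, a random control's should fall only slowly.
#'
#' @param object An `ml_experiment` (or a list of them to overlay, named by
#'   strategy).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ml_experiment <- function(object, ...) {
  plot_regret(list(object))
}

#' @rdname autoplot.ml_experiment
#' @param experiments A list of `ml_experiment` objects to overlay.
#' @export
plot_regret <- function(experiments, ...) {
  if (inherits(experiments, "ml_experiment")) experiments <- list(experiments)
  df <- purrr::map_dfr(experiments, tidy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$median_delta_ba,
                                   colour = .data$strategy,
                                   fill = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration",
                  y = expression(Delta * " balanced accuracy (median)"),
                  colour = "strategy", fill = "strategy") +
    ggplot2::theme_minimal()
}

#' Plot cumulative success-rate curves
#'
#' Fraction of datasets for which the recommender has proposed a
#' configuration scoring within each relative threshold of the dataset's
#' best known configuration, against cumulative configuration evaluations.
#'
#' @param experiments An `ml_experiment` or list of them.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_success_rate <- function(experiments, ...) {
  if (inherits(experiments, "ml_experiment")) experiments <- list(experiments)
  df <- purrr::map_dfr(experiments, tidy) |>
    tidyr::pivot_longer(dplyr::starts_with("success_rate_"),
                        names_to = "threshold", values_to = "success_rate",
                        names_prefix = "success_rate_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$evals, y = .data$success_rate,
                                   colour = .data$strategy,
                                   linetype = .data$threshold)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "configuration evaluations", y = "success rate",
                  colour = "strategy", linetype = "within") +
    ggplot2::theme_minimal()
}
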