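#' Plot a virtual experiment
#'
#' Draws each virtual individual's true dose-response curve on a log10
#' illuminance axis with the noisy measurements overlaid, the standard
#' visual summary of a simulated melatonin suppression experiment.
#'
#' @param object A `mel_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mel_experiment
#' @export
autoplot.mel_experiment <- function(object, ...) {
  grid <- attr(object, "grid")
  curves <- object |>
    dplyr::distinct(.data$individual_id, .data$a, .data$b) |>
    tidyr::expand_grid(lux = 10^seq(0, log10(max(grid)) + 0.2,
                                    length.out = 120)) |>
    dplyr::filter(.data$lux >= 1) |>
    dplyr::mutate(s = suppression(.data$lux, .data$a, .data$b))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$lux, y = .data$s,
                               group = .data$individual_id)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_point(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$lux, y = .data$measured_suppression),
      size = 0.6, alpha = 0.7
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Illuminance (photopic lux)",
                  y = "Melatonin suppression",
                  title = paste0("Virtual experiment (n = ",
                                 dplyr::n_distinct(object$individual_id),
                                 ", eta = ", attr(object, "eta"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot the fitted log10-ED50 distribution
#'
#' @param object A `mel_adist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mel_adist
#' @export
autoplot.mel_adist <- function(object, ...) {
  df <- tibble::tibble(a = object$grid, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$a50, linetype = "dashed") +
    ggplot2::labs(x = "a = log10(ED50)", y = "Density",
                  title = "Kernel density of individual sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a power grid
#'
#' Power against sample size, one line per heterogeneity level,
#' faceted by test size.
#'
#' @param object A `mel_power_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mel_power_grid
#' @export
autoplot.mel_power_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$N, y = .data$power,
                               colour = factor(.data$eta),
                               group = factor(.data$eta))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Sample size N", y = "Power (correct sign)",
                  colour = "eta") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Posterior predictive check plot for the log-b regression
#'
#' Overlays the raw `(a, b)` estimates on the 2.5-97.5 percent posterior
#' predictive ribbon and median curve.
#'
#' @param fit A `mel_regression`.
#' @param raw The raw-estimates table.
#' @param ... Passed to [ppc_regression()].
#' @return A ggplot object.
#' @export
plot_ppc_regression <- function(fit, raw, ...) {
  ribbon <- ppc_regression(fit, raw, ...)
  ggplot2::ggplot(ribbon, ggplot2::aes(x = .data$a)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(data = raw,
                        ggplot2::aes(x = .data$a, y = .data$b),
                        colour = "darkorange") +
    ggplot2::labs(x = "a = log10(ED50)", y = "b (curve shape)",
                  title = "Posterior predictive check: log b regression") +
    ggplot2::theme_minimal()
}
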