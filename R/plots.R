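# ggplot2 visualisations: log-log spacer-count histograms with fitted
# curves, stationary model distributions, and sweep trajectories.

#' Plot a fitted heavy-tailed distribution over the data
#'
#' Log-log plot of the empirical probability of each spacer count with the
#' fitted family overlaid.
#'
#' @param object An `ht_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ht_fit <- function(object, ...) {
  emp <- tibble::tibble(x = object$data, w = object$weights) |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop") |>
    dplyr::mutate(p = .data$w / sum(.data$w))
  xs <- seq(min(emp$x), max(emp$x))
  fitted <- tibble::tibble(x = xs, p = dist_pmf(object$spec, xs))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "spacers per array", y = "probability",
      title = sprintf("%s fit", object$spec$family),
      subtitle = paste(names(object$spec$params),
                       signif(unlist(object$spec$params), 3),
                       sep = " = ", collapse = ", ")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a stationary spacer distribution
#'
#' Log-log plot of the model's stationary class probabilities, optionally
#' with a fitted truncated power law overlaid.
#'
#' @param object A `stationary_result`.
#' @param fit Optional `ht_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stationary_result <- function(object, fit = NULL, ...) {
  df <- tidy(object) |> dplyr::filter(.data$probability > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$spacer_count,
                                        y = .data$probability)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spacers per array", y = "stationary probability",
                  title = "Stationary spacer distribution") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    fitted <- tibble::tibble(
      spacer_count = df$spacer_count,
      probability = dist_pmf(fit$spec, df$spacer_count)
    )
    p <- p + ggplot2::geom_line(data = fitted, colour = "firebrick",
                                linetype = "dashed")
  }
  p
}

#' Plot a parameter sweep of the fitted power-law exponent
#'
#' @param sweep_table Output of [sweep_dynamics()].
#' @return A ggplot object of fitted `alpha` against the varied value.
#' @export
plot_sweep <- function(sweep_table) {
  ggplot2::ggplot(dplyr::filter(sweep_table, !is.na(.data$alpha)),
                  ggplot2::aes(x = .data$value, y = .data$alpha)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "parameter value", y = "fitted alpha",
                  title = "Sensitivity of the power-law exponent") +
    ggplot2::theme_minimal()
}

#' Log-log histogram of a spacer-count dataset
#'
#' @param data Spacer-count tibble.
#' @param by Optional grouping column mapped to colour.
#' @return A ggplot object.
#' @export
plot_spacer_histogram <- function(data, by = NULL) {
  hist <- spacer_histogram(data, by = by)
  mapping <- if (is.null(by)) {
    ggplot2::aes(x = .data$spacer_count, y = .data$n_arrays)
  } else {
    ggplot2::aes(x = .data$spacer_count, y = .data$n_arrays,
                 colour = .data[[by]])
  }
  ggplot2::ggplot(hist, mapping) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spacers per array", y = "number of arrays") +
    ggplot2::theme_minimal()
}
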