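#' Plot a fitted dose-response model
#'
#' Survey points and the fitted power curve on log-log axes, the scale on
#' which the model is linear.
#'
#' @param object A `power_fit`.
#' @param points Optional survey-point tibble to overlay (required when the
#'   fit carries no data, e.g. [default_power_model()]).
#' @param muic_range MUIC range (ug/L) for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_fit <- function(object, points = NULL,
                               muic_range = c(10, 500), ...) {
  grid <- tibble::tibble(
    muic_ug_per_l = exp(seq(log(muic_range[1]), log(muic_range[2]),
                            length.out = 200))
  )
  grid$tgr_percent <- predict_tgr(object, grid$muic_ug_per_l)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$muic_ug_per_l,
                                          y = .data$tgr_percent)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Median urinary iodine concentration (µg/L)",
      y = "Total goiter rate (%)",
      title = sprintf("TGR = %.4g × MUIC^%.3g", object$alpha, object$beta)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = as_survey_points(points),
                                 alpha = 0.7, size = 2)
  }
  p
}

#' Bar chart of prevented cases by region
#'
#' @param report A `usi_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_prevented_cases <- function(report) {
  stopifnot(inherits(report, "usi_report"))
  df <- report$table2[report$table2$region != "Total", ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$region, .data$prevented_cases_thousands),
    y = .data$prevented_cases_thousands / 1000
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Prevented clinical IDD cases (millions)") +
    ggplot2::theme_minimal()
}

#' Bar chart of country counts by iodine-status class
#'
#' @param report A `usi_report`, or a counts tibble from [count_status()].
#' @return A ggplot object.
#' @export
plot_status_counts <- function(report) {
  counts <- if (inherits(report, "usi_report")) report$status_counts else report
  df <- counts[counts$region != "global", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n_countries,
                                   fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      deficient = "#b2182b", optimal = "#1a9850", above_optimal = "#fdae61"
    )) +
    ggplot2::labs(x = NULL, y = "Countries", fill = "Iodine status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
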