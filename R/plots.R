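#' Plot per-minute EWS component scores
#'
#' Step traces of the minute-by-minute component scores of one vital, one
#' panel per segment statistic (the per-minute counterpart of bedside EWS
#' charting).
#'
#' @param stream Tibble from [minute_ews_stream()].
#' @param vital Which vital to plot.
#' @return A ggplot object.
#' @export
plot_minute_scores <- function(stream, vital = "HR") {
  dd <- dplyr::filter(stream, .data$vital == !!vital)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$segment_index, y = .data$score)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~stat, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 3), breaks = 0:3) +
    ggplot2::labs(x = "minute", y = "EWS component score",
                  title = sprintf("Per-minute EWS component, %s", vital))
}

#' Plot absolute prediction errors
#'
#' Box plots of absolute error per statistic and horizon, one panel per
#' vital, with the naive persistence baseline alongside the model.
#'
#' @param records Prediction records from [loio_evaluate()].
#' @return A ggplot object.
#' @export
plot_absolute_error <- function(records) {
  long <- records |>
    dplyr::mutate(model = abs(.data$y_model - .data$y_true),
                  naive = abs(.data$y_naive - .data$y_true)) |>
    tidyr::pivot_longer(c("model", "naive"), names_to = "predictor",
                        values_to = "abs_error") |>
    dplyr::filter(is.finite(.data$abs_error))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = interaction(.data$statistic, .data$horizon),
                               y = .data$abs_error, fill = .data$predictor)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~vital, scales = "free_y") +
    ggplot2::labs(x = "statistic . horizon (h)", y = "absolute error")
}

#' Plot normalized EWS-error histograms
#'
#' Bin masses of the absolute EWS component error (0-3) for the model and
#' the naive baseline, per vital.
#'
#' @param report A `vc_report` from [evaluation_report()].
#' @return A ggplot object.
#' @export
plot_ews_error_histograms <- function(report) {
  long <- tidyr::pivot_longer(report$histograms, c("model", "naive"),
                              names_to = "predictor", values_to = "mass")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$error), y = .data$mass,
                                     fill = .data$predictor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~vital) +
    ggplot2::labs(x = "EWS component absolute error", y = "normalized mass")
}

#' @exportS3Method ggplot2::autoplot
autoplot.vc_report <- function(object, type = c("error", "histogram"), ...) {
  type <- match.arg(type)
  switch(type,
    error = plot_absolute_error(object$records),
    histogram = plot_ews_error_histograms(object)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
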