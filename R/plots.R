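#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a labelled stream
#'
#' Debug heatmap of the stream values (time on the x axis, location on the
#' y axis), optionally outlining the ground-truth event start times.
#'
#' @param object A `labeled_stream` (2D).
#' @param show_truth Mark true event start times with vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.labeled_stream <- function(object, show_truth = TRUE, ...) {
  stopifnot(object$dims == "2d")
  df <- tidyr::expand_grid(t = seq_len(nrow(object$values)),
                           loc = seq_len(ncol(object$values)))
  df$value <- as.vector(object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$loc,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time", y = "location", fill = "value") +
    ggplot2::theme_minimal()
  if (show_truth && nrow(object$registry) > 0L)
    p <- p + ggplot2::geom_vline(xintercept = object$registry$start_time,
                                 linetype = "dotted", colour = "red")
  p
}

#' Extracted events over the stream grid
#'
#' @param object An `event_set` (2D).
#' @param ... Unused.
#' @return A ggplot object with one colour per event.
#' @export
autoplot.event_set <- function(object, ...) {
  px <- object$pixels
  stopifnot(!"y" %in% names(px))
  ggplot2::ggplot(px, ggplot2::aes(x = .data$t, y = .data$loc,
                                   colour = factor(.data$event_id))) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(x = "time", y = "location", colour = "event") +
    ggplot2::theme_minimal()
}

#' Coefficient paths of a connected classifier across ages
#'
#' Shows how each coefficient varies with event age; larger penalties
#' flatten these paths toward a single shared classifier.
#'
#' @param object A `cc_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cc_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$age, y = .data$estimate,
                               colour = .data$term)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "event age", y = "coefficient") +
    ggplot2::theme_minimal()
}

#' Validation cost curves over the penalty grid
#'
#' Plots the validation data term, the penalty term and their total against
#' `lambda`, as produced by [select_lambda()].
#'
#' @param curves The `curves` tibble from [select_lambda()].
#' @return A ggplot object.
#' @export
plot_lambda_curves <- function(curves) {
  long <- tidyr::pivot_longer(curves, cols = c("data_term", "penalty_term",
                                               "total"),
                              names_to = "component", values_to = "cost")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$cost,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda), y = "validation cost") +
    ggplot2::theme_minimal()
}

#' Mean accuracy by age and classifier from an experiment report
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$age, y = .data$mean_accuracy,
                               colour = .data$classifier)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "event age", y = "mean test accuracy") +
    ggplot2::theme_minimal()
}
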