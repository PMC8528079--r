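#' Coefficient map of a windowed linear model
#'
#' Heatmap of the fitted coefficients over window offset (x) and feature
#' channel (y), split into nucleotide and loop-type panels. The offset-0
#' column shows the contribution of the scored nucleotide itself; decay
#' away from 0 reflects the locality of the degradation signal.
#'
#' @param object A `deg_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_model <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$channel != "(Intercept)", ]
  td$channel <- factor(td$channel, levels = c(NT_ALPHABET, LOOP_CHANNELS))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$offset, y = .data$channel,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel_kind),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(
      title = sprintf("Windowed linear degradation model: %s", object$target),
      x = "window offset (nt)", y = NULL, fill = "coefficient"
    ) +
    ggplot2::theme_minimal()
}

#' Per-data-type RMSE bars of a score report
#'
#' @param object A `score_report` from [mcrmse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_report <- function(object, ...) {
  ggplot2::ggplot(object$per_type,
                  ggplot2::aes(x = .data$data_type, y = .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mcrmse, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "column RMSE",
                  title = sprintf("MCRMSE = %.4f", object$mcrmse)) +
    ggplot2::theme_minimal()
}

#' Measured vs predicted profile for one construct
#'
#' Per-nucleotide measured values (with error ribbons where available)
#' overlaid with model predictions for one construct and data type.
#'
#' @param constructs Construct tibble.
#' @param predictions Long prediction tibble (`id`, `position`,
#'   `data_type`, `value`).
#' @param id Construct id to plot.
#' @param data_type Data type to plot.
#' @return A ggplot object.
#' @export
plot_profile <- function(constructs, predictions, id, data_type) {
  truth <- constructs_to_long(constructs)
  truth <- truth[truth$id == id & truth$data_type == data_type, ]
  pred <- predictions[predictions$id == id &
                        predictions$data_type == data_type, ]
  if (!nrow(truth)) abort(sprintf("No measured profile for '%s'/%s.",
                                  id, data_type))
  ggplot2::ggplot(truth, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$error,
                                      ymax = .data$value + .data$error),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value, colour = "measured")) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(y = .data$value, colour = "predicted")) +
    ggplot2::scale_colour_manual(values = c(measured = "black",
                                            predicted = "#b2182b")) +
    ggplot2::labs(x = "position (nt)", y = data_type, colour = NULL,
                  title = id) +
    ggplot2::theme_minimal()
}

#' Motif-aggregated signal plot
#'
#' Bar chart of a per-nucleotide signal averaged within structure motif
#' classes (see [aggregate_by_motif()]), the view used to compare how
#' models and measurements rank motifs such as triloops versus stems.
#'
#' @param motif_means Tibble from [aggregate_by_motif()] (optionally
#'   row-bound over several signals with a `signal` column).
#' @return A ggplot object.
#' @export
plot_motif_means <- function(motif_means) {
  aes <- if ("signal" %in% names(motif_means)) {
    ggplot2::aes(x = .data$class, y = .data$mean, fill = .data$signal)
  } else {
    ggplot2::aes(x = .data$class, y = .data$mean)
  }
  ggplot2::ggplot(motif_means, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
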