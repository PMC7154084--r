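#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_tile geom_col
#'   geom_errorbar geom_hline geom_line scale_y_log10 labs theme_minimal
#'   scale_fill_viridis_c annotation_raster coord_fixed geom_abline
#' @export
ggplot2::autoplot

#' @export
autoplot.scalogram <- function(object, ...) {
  # energy is n_freqs x n_times, column-major: frequency varies fastest
  df <- tidyr::expand_grid(
    time = object$times_s, freq = object$freqs_hz) |>
    mutate(energy = as.vector(object$energy))
  ggplot(df, aes(.data$time, .data$freq,
                 fill = log10(.data$energy + 1e-12))) +
    geom_raster() +
    scale_y_log10() +
    scale_fill_viridis_c(name = "log10 energy") +
    labs(x = "time (s)", y = "frequency (Hz)",
         title = sprintf("Morlet scalogram, channel %s",
                         as.character(object$channel_id))) +
    theme_minimal()
}

#' @export
autoplot.tiled_image <- function(object, ...) {
  d <- dim(object$raster)
  ggplot() +
    annotation_raster(object$raster, xmin = 0, xmax = d[2],
                      ymin = 0, ymax = d[1]) +
    ggplot2::xlim(0, d[2]) + ggplot2::ylim(0, d[1]) +
    coord_fixed() +
    labs(title = sprintf("%d x %d scalogram matrix", object$grid[1],
                         object$grid[2]),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$accuracy |>
    group_by(.data$subject) |>
    summarise(mean = mean(.data$accuracy), sd = stats::sd(.data$accuracy),
              .groups = "drop")
  ggplot(df, aes(factor(.data$subject), .data$mean)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    geom_hline(yintercept = object$chance_level, linetype = "dashed") +
    labs(x = "subject", y = "decoding accuracy (%)",
         title = sprintf("%s decoding, %s stage (dashed: chance level)",
                         object$method, object$stage)) +
    theme_minimal()
}

#' @export
autoplot.confusion_summary <- function(object, ...) {
  df <- tidy.confusion_summary(object)
  ggplot(df, aes(.data$predicted, .data$truth, fill = .data$count)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$count), colour = "white") +
    scale_fill_viridis_c() +
    labs(x = "predicted", y = "true") +
    theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param auc a [roc_auc_ovr()] result.
#' @return a ggplot object.
#' @export
plot_roc <- function(auc) {
  ggplot(auc$roc_points, aes(.data$fpr, .data$tpr,
                             colour = factor(.data$class))) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    coord_fixed() +
    labs(x = "false positive rate", y = "true positive rate",
         colour = "class",
         title = sprintf("One-vs-rest ROC (macro AUC %.3f)",
                         auc$macro_auc)) +
    theme_minimal()
}
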