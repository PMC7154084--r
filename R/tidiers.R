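#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.ann_model <- function(x, ...) x$history

#' @export
glance.ann_model <- function(x, ...) {
  tibble(hidden_nodes = x$cfg$hidden_nodes,
         learning_rate = x$cfg$learning_rate,
         epochs_run = nrow(x$history), best_epoch = x$best_epoch,
         val_loss = x$val_loss,
         val_accuracy = x$history$val_accuracy[x$best_epoch],
         n_parameters = length(x$W1) + length(x$b1) +
           length(x$W2) + length(x$b2))
}

#' @export
tidy.cnn_model <- function(x, ...) x$history

#' @export
glance.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
  tibble(conv_blocks = sum(vapply(x$layers, function(l) l$type == "conv",
                                  logical(1))),
         learning_rate = x$cfg$learning_rate,
         validation_events = nrow(x$history), best_event = x$best_event,
         val_loss = x$val_loss, n_parameters = np)
}

#' @export
tidy.confusion_summary <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion),
                          responseName = "count")) |>
    stats::setNames(c("truth", "predicted", "count"))
}

#' @export
glance.confusion_summary <- function(x, ...) {
  tibble(n = sum(x$confusion),
         average_accuracy = x$average_accuracy,
         overall_accuracy = x$overall_accuracy)
}

#' @export
tidy.eval_report <- function(x, ...) x$accuracy

#' @export
glance.eval_report <- function(x, ...) {
  tibble(stage = x$stage, method = x$method,
         mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
         average_class_accuracy = x$confusion$average_accuracy,
         overall_accuracy = x$confusion$overall_accuracy,
         macro_auc = x$auc$macro_auc, chance_level = x$chance_level,
         p_vs_chance = if (!is.null(x$vs_chance)) x$vs_chance$p_value
                       else NA_real_)
}

#' @export
tidy.split_plan <- function(x, ...) x$assignment
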