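# Broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a trained CNN's history
#'
#' @param x A trained `eeg_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `val_accuracy`.
#' @export
tidy.eeg_cnn <- function(x, ...) {
  if (!x$trained) stop_invalid("model is not trained")
  x$history
}

#' One-row summary of a trained CNN
#'
#' @param x A trained `eeg_cnn`.
#' @param ... Unused.
#' @return Tibble: classes, arrangement, epochs, parameter count, final loss
#'   and validation accuracy.
#' @export
glance.eeg_cnn <- function(x, ...) {
  if (!x$trained) stop_invalid("model is not trained")
  tibble::tibble(
    n_classes = x$config$n_classes,
    arrangement = x$kind,
    use_batchnorm = x$config$use_batchnorm,
    epochs = nrow(x$history),
    n_parameters = sum(vapply(x$params, length, integer(1))),
    final_loss = tail(x$history$loss, 1),
    final_val_accuracy = tail(x$history$val_accuracy, 1)
  )
}

#' @describeIn tidy.eeg_cnn Per-fold accuracies of a cross-validation run.
#' @export
tidy.eval_result <- function(x, ...) {
  dplyr::mutate(x$per_fold, arrangement = x$arrangement, dataset = x$dataset,
                batchnorm = x$batchnorm)
}

#' One-row summary of a cross-validation result
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return Tibble with mean validation/test accuracy and the run metadata.
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(
    arrangement = x$arrangement, dataset = x$dataset, batchnorm = x$batchnorm,
    validation_accuracy = x$validation_accuracy,
    test_accuracy = x$test_accuracy,
    n_folds = nrow(x$per_fold), n_classes = x$n_classes, seed = x$seed
  )
}

#' Training-history curve
#'
#' @param object A trained `eeg_cnn`.
#' @param ... Unused.
#' @return A ggplot of loss and validation accuracy against epoch.
#' @export
autoplot.eeg_cnn <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("loss", "val_accuracy"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "CNN training history")
}

#' Comparison-grid plot
#'
#' @param object An `arrangement_comparison`.
#' @param ... Unused.
#' @return A ggplot of mean test accuracy by arrangement, faceted by dataset.
#' @export
autoplot.arrangement_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$arrangement,
                               y = .data$test_accuracy,
                               fill = factor(.data$batchnorm))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(x = "input arrangement", y = "mean test accuracy (%)",
                  fill = "batch norm")
}
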