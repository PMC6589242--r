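# Identification accuracy, the threefold cross-validation protocol, and the
# arrangement x dataset x batch-norm comparison grid.

#' Identification accuracy (percent)
#'
#' `100 * (correct predictions) / (predictions made)`.
#'
#' @param predicted,truth Equal-length, non-empty label vectors.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
#' @examples
#' accuracy(c("a", "b", "b", "b"), c("a", "b", "a", "b"))
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(truth) == 0L) {
    stop_invalid("`predicted` and `truth` must be non-empty")
  }
  if (length(predicted) != length(truth)) {
    stop_invalid("`predicted` and `truth` must have equal length")
  }
  100 * sum(predicted == truth) / length(predicted)
}

cohort_conditions <- function(cohort, dataset) {
  conds <- switch(dataset, "REC" = "REC", "REO" = "REO",
                  "REC+REO" = c("REC", "REO"))
  have <- unique(vapply(cohort, `[[`, character(1), "condition"))
  missing <- setdiff(conds, have)
  if (length(missing)) {
    stop_invalid("cohort lacks condition(s): ", paste(missing, collapse = ", "))
  }
  Filter(function(r) r$condition %in% conds, cohort)
}

#' Threefold cross-validated identification
#'
#' Runs the full protocol for one arrangement and dataset choice: segment the
#' recordings into 1 s windows; for each fold build the rotated 25/5/30
#' split, derive the global channel order from the pooled training segments
#' (M3/I3 only), arrange all three sets, train the CNN, and score validation
#' and test accuracy. Reported accuracies are fold means. The mini-batch
#' size defaults to 100 for a single condition and 200 for REC+REO; fold `f`
#' trains with seed `train_cfg$seed + f`.
#'
#' @param cohort An `eeg_cohort` (or list of `eeg_recording`s).
#' @param arrangement One of [arrangement_kinds()].
#' @param dataset `"REC"`, `"REO"` or `"REC+REO"`.
#' @param use_batchnorm Toggle batch normalization (default `FALSE`).
#' @param train_cfg A [train_config()]; its `batch_size` is overridden by the
#'   dataset rule unless `override_batch = FALSE`.
#' @param k Number of folds (default 3).
#' @param energy Energy definition for M2/I2 (see [energy_matrix()]).
#' @param shuffle_labels Permute training/validation subject labels (a null
#'   control that should score at the chance floor `100 / n_classes`).
#' @param override_batch Apply the 100/200 mini-batch rule (default `TRUE`).
#' @return An `eval_result` with per-fold and mean accuracies.
#' @export
crossvalidate <- function(cohort, arrangement, dataset = c("REC", "REO", "REC+REO"),
                          use_batchnorm = FALSE, train_cfg = train_config(),
                          k = 3L, energy = c("hilbert", "analytic_magnitude"),
                          shuffle_labels = FALSE, override_batch = TRUE) {
  arrangement <- match.arg(arrangement, arrangement_kinds())
  dataset <- match.arg(dataset)
  energy <- match.arg(energy)
  if (!is_count(k, min = 2L)) stop_invalid("`k` must be an integer >= 2")
  recs <- cohort_conditions(cohort, dataset)
  segments <- unlist(lapply(recs, segment_recording), recursive = FALSE)
  subjects <- sort(unique(vapply(segments, `[[`, integer(1), "subject_id")))
  n_classes <- length(subjects)
  if (override_batch) {
    train_cfg$batch_size <- if (dataset == "REC+REO") 200L else 100L
  }
  folds <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    split <- split_segments(segments, fold_id = f)
    order <- NULL
    if (arrangement %in% c("M3", "I3")) {
      order <- reorder_channels(correlation_matrix(split$train))
    }
    arr <- function(set) lapply(set, arrange_segment, kind = arrangement,
                                order = order, energy = energy)
    split$train <- arr(split$train)
    split$validation <- arr(split$validation)
    split$test <- arr(split$test)
    if (shuffle_labels) {
      split <- with_seed(train_cfg$seed + 7919L * (f + 1L), {
        for (set in c("train", "validation")) {
          labs <- vapply(split[[set]], `[[`, integer(1), "subject_id")
          labs <- sample(labs)
          for (i in seq_along(split[[set]])) {
            split[[set]][[i]]$subject_id <- labs[i]
          }
        }
        split
      })
    }
    fold_cfg <- train_cfg
    fold_cfg$seed <- train_cfg$seed + f
    model <- build_model(cnn_config(n_classes, use_batchnorm = use_batchnorm))
    model <- train_model(model, split, fold_cfg)
    score <- function(set) {
      pred <- predict(model, set)
      accuracy(pred$.pred_class,
               vapply(set, `[[`, integer(1), "subject_id"))
    }
    folds[[f + 1L]] <- tibble::tibble(
      fold = f,
      val_accuracy = score(split$validation),
      test_accuracy = score(split$test)
    )
  }
  per_fold <- dplyr::bind_rows(folds)
  structure(
    list(arrangement = arrangement, dataset = dataset,
         batchnorm = isTRUE(use_batchnorm),
         validation_accuracy = mean(per_fold$val_accuracy),
         test_accuracy = mean(per_fold$test_accuracy),
         per_fold = per_fold, n_classes = n_classes,
         seed = train_cfg$seed, shuffled = isTRUE(shuffle_labels)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s on %s (%d subjects%s%s): validation %.2f%%, test %.2f%% over %d folds\n",
    x$arrangement, x$dataset, x$n_classes,
    if (x$batchnorm) ", BN" else "",
    if (x$shuffled) ", shuffled labels" else "",
    x$validation_accuracy, x$test_accuracy, nrow(x$per_fold)
  ))
  invisible(x)
}

#' Compare arrangements across datasets
#'
#' Runs [crossvalidate()] for every combination of arrangement, dataset and
#' batch-norm setting and collects one row per cell, mirroring the shape of
#' the published comparison tables, plus a best-arrangement summary per
#' dataset.
#'
#' @param cohort An `eeg_cohort`.
#' @param arrangements Character vector of arrangement kinds.
#' @param datasets Character vector from `c("REC", "REO", "REC+REO")`.
#' @param bn_settings Logical vector of batch-norm settings (default `FALSE`).
#' @param train_cfg A [train_config()].
#' @param k Folds per cell (default 3).
#' @return An `arrangement_comparison` tibble: `arrangement`, `dataset`,
#'   `batchnorm`, `validation_accuracy`, `test_accuracy`, `per_fold`
#'   (list-column); the per-dataset best rows are in
#'   `attr(, "best_by_dataset")` and shown by `summary()`.
#' @export
compare_arrangements <- function(cohort, arrangements = arrangement_kinds(),
                                 datasets = c("REC", "REO", "REC+REO"),
                                 bn_settings = FALSE,
                                 train_cfg = train_config(), k = 3L) {
  if (length(arrangements) == 0L || length(datasets) == 0L) {
    stop_invalid("`arrangements` and `datasets` must be non-empty")
  }
  grid <- tidyr::expand_grid(arrangement = arrangements, dataset = datasets,
                             batchnorm = bn_settings)
  rows <- purrr::pmap(grid, function(arrangement, dataset, batchnorm) {
    r <- crossvalidate(cohort, arrangement, dataset,
                       use_batchnorm = batchnorm, train_cfg = train_cfg, k = k)
    tibble::tibble(arrangement = r$arrangement, dataset = r$dataset,
                   batchnorm = r$batchnorm,
                   validation_accuracy = r$validation_accuracy,
                   test_accuracy = r$test_accuracy,
                   per_fold = list(r$per_fold))
  })
  out <- dplyr::bind_rows(rows)
  best <- out |>
    dplyr::group_by(.data$dataset) |>
    dplyr::slice_max(.data$test_accuracy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  structure(out, best_by_dataset = best,
            class = c("arrangement_comparison", class(out)))
}

#' @export
summary.arrangement_comparison <- function(object, ...) {
  cat("Best arrangement per dataset (by mean test accuracy):\n")
  print(attr(object, "best_by_dataset")[
    c("dataset", "arrangement", "validation_accuracy", "test_accuracy")])
  invisible(attr(object, "best_by_dataset"))
}

#' Chance-level accuracy
#'
#' The expected accuracy (percent) of label-independent prediction among
#' `n_classes` enrolled subjects.
#'
#' @param n_classes Number of classes.
#' @return `100 / n_classes`.
#' @export
chance_floor <- function(n_classes) 100 / n_classes
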