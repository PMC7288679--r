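#' Build a labeled fingerprint dataset from positive and negative compounds
#'
#' @param positives,negatives Tibbles with `compound_id` and `fp`
#'   (fingerprint list-column) columns; rows with `NULL` fingerprints are
#'   not allowed.
#' @return A tibble with columns `compound_id`, `fp`, `label` (factor with
#'   levels `negative`, `positive`).
#' @export
build_dataset <- function(positives, negatives) {
  for (d in list(positives, negatives)) {
    stopifnot(is.data.frame(d), all(c("compound_id", "fp") %in% names(d)))
    if (any(vapply(d$fp, is.null, logical(1)))) {
      stop("dataset rows must all carry fingerprints", call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(
    tibble::tibble(compound_id = positives$compound_id, fp = positives$fp,
                   label = "positive"),
    tibble::tibble(compound_id = negatives$compound_id, fp = negatives$fp,
                   label = "negative")
  )
  dup <- unique(out$compound_id[duplicated(out$compound_id)])
  if (length(dup) > 0L) {
    stop("duplicate compound_id in dataset: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  out$label <- factor(out$label, levels = c("negative", "positive"))
  out
}

#' Split a labeled dataset into training and testing subsets
#'
#' Plain (unstratified) seeded random split: `round(test_fraction * n)` rows
#' go to the test set, the rest to training. With the pipeline's 10:1
#' negative ratio both classes are present in both subsets with overwhelming
#' probability at realistic sizes; a single-class *input* is rejected.
#'
#' @param data Labeled dataset from [build_dataset()].
#' @param test_fraction Fraction of rows assigned to the test set
#'   (default 0.3). Zero yields an empty test set with a warning.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (labeled tibbles) and
#'   attributes `test_fraction` and `seed`.
#' @export
split_dataset <- function(data, test_fraction = 0.3, seed = 1L) {
  stopifnot(is.data.frame(data), "label" %in% names(data),
            test_fraction >= 0, test_fraction < 1)
  if (nrow(data) < 4L) {
    stop("dataset too small to split (need at least 4 rows)", call. = FALSE)
  }
  if (dplyr::n_distinct(data$label) < 2L) {
    stop("cannot split a single-class dataset", call. = FALSE)
  }
  n_test <- round(test_fraction * nrow(data))
  if (n_test == 0L) {
    warning("test_fraction ", test_fraction, " yields an empty test set",
            call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(data), n_test))
  structure(
    list(train = data[setdiff(seq_len(nrow(data)), idx), , drop = FALSE],
         test = data[sort(idx), , drop = FALSE]),
    test_fraction = test_fraction, seed = seed,
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> train: ", nrow(x$train), " rows, test: ",
      nrow(x$test), " rows (test_fraction = ", attr(x, "test_fraction"),
      ")\n", sep = "")
  invisible(x)
}

#' Train the random-forest bioactivity classifier
#'
#' Fits an ensemble of `n_trees` decision trees, each on a bootstrap
#' resample of the training rows with random feature subsetting at every
#' split (`sqrt` of the 1024 fingerprint bits, Gini impurity, unlimited
#' depth — the standard random-forest defaults). Class probability of a new
#' compound is the fraction of trees voting positive. Training is seeded and
#' fully reproducible.
#'
#' @param data Labeled dataset (both classes present).
#' @param n_trees Number of component trees (default 100).
#' @param seed Integer seed.
#' @return A `bioactivity_model` object.
#' @export
train_forest <- function(data, n_trees = 100L, seed = 1L) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("cannot train on an empty dataset", call. = FALSE)
  if (dplyr::n_distinct(data$label) < 2L) {
    stop("cannot train on a single-class dataset", call. = FALSE)
  }
  x <- fp_matrix(data$fp)
  colnames(x) <- paste0("bit", seq_len(ncol(x)))
  y <- data$label
  forest <- withr::with_seed(
    seed,
    randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees))
  )
  structure(
    list(forest = forest, n_trees = as.integer(n_trees), seed = seed,
         n_positive = sum(y == "positive"), n_negative = sum(y == "negative"),
         n_bits = ncol(x)),
    class = "bioactivity_model"
  )
}

#' Retrain the final model on the full dataset
#'
#' After evaluation on the held-out split, the model actually used to score
#' food compounds is refit on *all* labeled data. Call [evaluate_model()]
#' on the split-trained model first; metrics always refer to the held-out
#' test set, never to this final model.
#'
#' @inheritParams train_forest
#' @return A `bioactivity_model`.
#' @export
retrain_full <- function(data, n_trees = 100L, seed = 1L) {
  train_forest(data, n_trees = n_trees, seed = seed)
}

#' @export
print.bioactivity_model <- function(x, ...) {
  cat("<bioactivity_model> random forest, ", x$n_trees, " trees, trained on ",
      x$n_positive, " positives / ", x$n_negative, " negatives (",
      x$n_bits, "-bit fingerprints)\n", sep = "")
  invisible(x)
}

#' Predict bioactivity probabilities for fingerprints
#'
#' The score of a compound is the fraction of ensemble trees voting for the
#' positive class, a number in `[0, 1]`.
#'
#' @param model A trained `bioactivity_model`.
#' @param fps List of `chem_fp` fingerprints (or a 0/1 matrix, one row per
#'   compound).
#' @return Numeric vector of scores, one per fingerprint; `numeric(0)` for
#'   empty input.
#' @export
predict_proba <- function(model, fps) {
  if (!inherits(model, "bioactivity_model") || is.null(model$forest)) {
    stop("`model` must be a trained bioactivity_model", call. = FALSE)
  }
  x <- fp_matrix(fps)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != model$n_bits) {
    stop("fingerprint length ", ncol(x), " does not match the model's ",
         model$n_bits, call. = FALSE)
  }
  colnames(x) <- paste0("bit", seq_len(ncol(x)))
  unname(stats::predict(model$forest, newdata = x, type = "prob")[, "positive"])
}

#' Confusion counts and precision/recall/F1 from raw counts
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 is their
#' harmonic mean 2 * precision * recall / (precision + recall). A degenerate
#' denominator yields 0 by convention.
#'
#' @param tp,fp,fn,tn Non-negative integer confusion counts.
#' @return A `model_metrics` object (also a one-row tibble) with columns
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @examples
#' classification_metrics(tp = 8, fp = 2, fn = 4, tn = 86)
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  out <- tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                        precision = precision, recall = recall, f1 = f1)
  class(out) <- c("model_metrics", class(out))
  out
}

#' Evaluate a trained model on a held-out test set
#'
#' Scores the test fingerprints and thresholds them (predicted positive when
#' score strictly exceeds `decision_threshold`), then computes the confusion
#' matrix and precision/recall/F1 via [classification_metrics()].
#'
#' @param model A trained `bioactivity_model`.
#' @param test Labeled dataset (the `test` element of [split_dataset()]).
#' @param decision_threshold Score cutoff for calling a prediction positive
#'   (default 0.5).
#' @return A `model_metrics` one-row tibble.
#' @export
evaluate_model <- function(model, test, decision_threshold = 0.5) {
  stopifnot(is.data.frame(test), nrow(test) > 0L)
  scores <- predict_proba(model, test$fp)
  pred_pos <- scores > decision_threshold
  actual_pos <- test$label == "positive"
  classification_metrics(
    tp = sum(pred_pos & actual_pos),
    fp = sum(pred_pos & !actual_pos),
    fn = sum(!pred_pos & actual_pos),
    tn = sum(!pred_pos & !actual_pos)
  )
}

#' Shuffle dataset labels (permutation null control)
#'
#' Randomly permutes the class labels while keeping the fingerprints fixed.
#' Training on shuffled labels and evaluating on a held-out split estimates
#' the no-signal baseline: held-out F1 should collapse to chance, which is a
#' standard leakage check for the pipeline.
#'
#' @param data Labeled dataset.
#' @param seed Integer seed.
#' @return The dataset with permuted labels.
#' @export
shuffle_dataset_labels <- function(data, seed = 1L) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  data$label <- withr::with_seed(seed, sample(data$label))
  data
}
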