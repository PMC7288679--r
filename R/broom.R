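#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted bioactivity model
#'
#' One row per fingerprint bit, with its Gini importance in the forest,
#' ordered by decreasing importance. Bits tied to the planted/selected
#' structural signal surface at the top.
#'
#' @param x A `bioactivity_model`.
#' @param ... Unused.
#' @return Tibble with columns `bit` (0-based index) and `importance`.
#' @exportS3Method generics::tidy
tidy.bioactivity_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(
    bit = as.integer(sub("^bit", "", rownames(imp))) - 1L,
    importance = unname(imp[, "MeanDecreaseGini"])
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$bit)
}

#' Glance at a fitted bioactivity model
#'
#' @param x A `bioactivity_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_trees`, `n_positive`, `n_negative`,
#'   `oob_error` (out-of-bag error rate).
#' @exportS3Method generics::glance
glance.bioactivity_model <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    n_positive = x$n_positive,
    n_negative = x$n_negative,
    oob_error = unname(x$forest$err.rate[x$forest$ntree, "OOB"])
  )
}

#' Tidy held-out evaluation metrics
#'
#' @param x A `model_metrics` object.
#' @param ... Unused.
#' @return Long tibble with columns `metric` and `value`.
#' @exportS3Method generics::tidy
tidy.model_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("tp", "fp", "fn", "tn", "precision", "recall", "f1"),
    value = c(x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1)
  )
}

#' Glance at held-out evaluation metrics
#'
#' @param x A `model_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with `precision`, `recall`, `f1`, `n_test`.
#' @exportS3Method generics::glance
glance.model_metrics <- function(x, ...) {
  tibble::tibble(
    precision = x$precision, recall = x$recall, f1 = x$f1,
    n_test = x$tp + x$fp + x$fn + x$tn
  )
}

#' Glance at a full pipeline run
#'
#' @param x A `screen_run`.
#' @param ... Unused.
#' @return One-row tibble of stage counts and held-out metrics.
#' @exportS3Method generics::glance
glance.screen_run <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble::tibble(
    n_positive = cnt$n_positive,
    n_negative = cnt$n_negative,
    n_train = cnt$n_train,
    n_test = cnt$n_test,
    n_food_scored = cnt$n_food_scored,
    n_reported = cnt$n_reported,
    precision = x$metrics$precision,
    recall = x$metrics$recall,
    f1 = x$metrics$f1
  )
}
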