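#' Plot the top-scoring food compounds of a prediction report
#'
#' Lollipop chart of predicted bioactivity probability for the highest
#' scoring food compounds, coloured by novelty (whether the compound lacks
#' recorded activity evidence for the target).
#'
#' @param object A `prediction_report` from [filter_and_annotate()].
#' @param n_top Number of compounds shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prediction_report <- function(object, n_top = 20L, ...) {
  top <- utils::head(object, n_top)
  top$name <- factor(top$name, levels = rev(top$name))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$score, y = .data$name,
                                    colour = .data$novel)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$name),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "predicted bioactivity probability", y = NULL,
                  colour = "novel") +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of a pipeline run
#'
#' Histogram of predicted bioactivity probability over all scored food
#' compounds, with the reporting threshold marked. In a well-behaved run
#' most of the library sits near zero and a small tail clears the
#' threshold.
#'
#' @param object A `screen_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.screen_run <- function(object, ...) {
  thr <- object$manifest$config$score_threshold
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "predicted bioactivity probability",
                  y = "food compounds") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
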