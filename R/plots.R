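#' Heatmap of an APC association matrix
#'
#' @param object A fitted `"apc"` model.
#' @param ... Unused.
#' @return A ggplot: classes on the y axis, features on the x axis, tile
#'   fill = matrix weight.  Rows sum to zero componentwise, so the two rows
#'   of a two-class model mirror each other.
#' @method autoplot apc
#' @export
autoplot.apc <- function(object, ...) {
  d <- tidy(object)
  d$feature <- factor(d$feature, levels = object$feature_names)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$class,
                                  fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "feature", y = "class", fill = "weight",
                  title = "APC association matrix") +
    ggplot2::theme_minimal()
}

#' Accuracy distribution of an evaluation
#'
#' @param object An `"apc_evaluation"`.
#' @param ... Unused.
#' @return A ggplot histogram of per-unit accuracies with the mean marked.
#' @method autoplot apc_evaluation
#' @export
autoplot.apc_evaluation <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!d$failed, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(d$accuracy), linetype = 2) +
    ggplot2::labs(
      x = "accuracy", y = "evaluation units",
      title = sprintf("%s under %s validation", attr(object, "classifier"),
                      attr(object, "plan_kind"))) +
    ggplot2::theme_minimal()
}

#' Learning-curve plot
#'
#' @param object An `"apc_learning_curve"`.
#' @param ... Unused.
#' @return A ggplot of mean accuracy (with a +/- 1 sd ribbon) against the
#'   training fraction.
#' @method autoplot apc_learning_curve
#' @export
autoplot.apc_learning_curve <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction,
                                  y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training fraction", y = "mean accuracy",
                  title = "Learning curve") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
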