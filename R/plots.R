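# ggplot2 helpers for screens and calibrations.

#' Plot the precision-recall curve of one or more screens
#'
#' @param screens A `ranked_screen` or a named list of them.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(screens) {
  df <- .curve_df(screens, pr_curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$screen)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of one or more screens
#'
#' @inheritParams plot_pr_curve
#' @return A ggplot object.
#' @export
plot_roc_curve <- function(screens) {
  df <- .curve_df(screens, roc_curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$screen)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

.curve_df <- function(screens, fn) {
  if (is.data.frame(screens)) screens <- list(screen = screens)
  if (is.null(names(screens))) {
    names(screens) <- paste0("screen", seq_along(screens))
  }
  bind_rows(lapply(names(screens), function(nm) {
    mutate(fn(screens[[nm]]), screen = nm)
  }))
}

#' Plot a fitted score-to-precision calibration
#'
#' @param cal A `precision_calibration`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(cal) {
  stopifnot(inherits(cal, "precision_calibration"))
  ggplot2::ggplot(cal$breakpoints,
                  ggplot2::aes(x = .data$score, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Raw score", y = "Predicted precision",
                  title = cal$method %||% NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a ranked screen (its PR curve)
#' @param object A `ranked_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ranked_screen
#' @export
autoplot.ranked_screen <- function(object, ...) {
  plot_pr_curve(object)
}
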