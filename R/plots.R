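# ggplot2 displays for the package's result objects.

#' Plot a grand-average ERP time course
#'
#' @param object A `grand_average`.
#' @param channels Channels to draw (default `c("C1", "C2")` where present,
#'   else the first two).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grand_average <- function(object, channels = NULL, ...) {
  if (is.null(channels)) {
    channels <- intersect(c("C1", "C2"), object$channels)
    if (length(channels) == 0) {
      channels <- utils::head(object$channels, 2)
    }
  }
  df <- dplyr::filter(tidy.grand_average(object),
                      .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude,
                                   colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time relative to movement onset (s)",
      y = "amplitude (µV)",
      colour = NULL,
      title = sprintf("grand average (%d epochs)", object$n_epochs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot fold balanced accuracies of condition reports
#'
#' @param object A `condition_report` (several may be row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$montage, .data$ba,
                                       fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = NULL, y = "balanced accuracy", fill = "condition") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a window-prediction sequence with its relabeled truth
#'
#' @param object A `trial_predictions` tibble.
#' @param truth Optional `ground_truth_labels` from [relabel_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_predictions <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$end,
                                            .data$probability)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "window end relative to onset (s)",
                  y = "LRP probability") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    df <- dplyr::mutate(truth, y = ifelse(.data$truth == "LRP", 1, 0))
    p <- p + ggplot2::geom_step(
      data = df,
      ggplot2::aes(x = .data$start + 1, y = .data$y),
      colour = "red", linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
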