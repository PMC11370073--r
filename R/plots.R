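# ggplot2 presentation methods for the main result types.

#' Plot marginal-mean trajectories
#'
#' Estimated marginal means by age and sex with 95% confidence ribbons.
#'
#' @param object A [marginal_means()] tibble.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.marginal_means <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$age, y = .data$estimate,
    colour = .data$sex, fill = .data$sex
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Age (years)",
      y = paste0(unique(object$outcome), " (min/day)"),
      colour = "Sex", fill = "Sex"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pooled confusion matrix
#'
#' Heatmap of the leave-one-subject-out confusion matrix with per-cell
#' counts; rows are true classes, columns predictions.
#'
#' @param object A `class_metrics` object (e.g. from [loso_cv()]).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.class_metrics <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("truth", "predicted", "n")
  ggplot2::ggplot(cm, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Windows") +
    ggplot2::theme_minimal()
}

#' Plot daily behaviour composition
#'
#' Stacked daily minutes by intensity for each monitored day.
#'
#' @param summaries Daily summaries (see [summarize_days()]).
#'
#' @return A ggplot object.
#' @export
plot_daily_summaries <- function(summaries) {
  long <- summaries |>
    dplyr::select("subject_id", "date", "sedentary", "lpa", "energetic_play") |>
    tidyr::pivot_longer(c("sedentary", "lpa", "energetic_play"),
      names_to = "behaviour", values_to = "minutes"
    ) |>
    dplyr::mutate(behaviour = factor(
      .data$behaviour,
      levels = c("sedentary", "lpa", "energetic_play")
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$minutes, fill = .data$behaviour)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "Date", y = "Minutes/day", fill = "Behaviour") +
    ggplot2::theme_minimal()
}
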