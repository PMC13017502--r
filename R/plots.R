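# ggplot2 displays for the main result types.

#' Plot a training distribution
#'
#' Rank-frequency bar chart of the probability mass (log-scaled y axis for
#' skewed distributions).
#'
#' @param spec a [zipf_spec()] or [composite_spec()].
#' @param max_rank truncate the display to the first ranks.
#' @return a ggplot object.
#' @export
plot_distribution <- function(spec, max_rank = 50) {
  df <- tidy(spec)
  df <- df[df$rank <= max_rank, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "rank", y = "probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.icw_fit <- function(object, ...) {
  if (is.null(object$history)) {
    abort("fit has no checkpoint history (eval_every was Inf)")
  }
  df <- tidyr::pivot_longer(object$history,
                            cols = c("acc_train", "acc_ic", "acc_iw"),
                            names_to = "block", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$accuracy,
                                   colour = .data$block)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$task$chance, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "training step", y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.icw_sweep <- function(object, ...) {
  df <- object$metrics
  colour_var <- if ("alpha" %in% names(df)) "alpha" else "learner_class"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$acc_ic, y = .data$acc_iw,
                                   colour = factor(.data[[colour_var]]))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "in-context test accuracy", y = "in-weights test accuracy",
                  colour = colour_var) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.icw_curriculum <- function(object, ...) {
  if (is.null(object$trajectories)) {
    abort("curriculum run has no trajectories (eval_every was Inf)")
  }
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$acc_ic, y = .data$acc_iw,
                               colour = .data$condition,
                               group = interaction(.data$condition, .data$model))) +
    ggplot2::geom_path(alpha = 0.5, arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "in-context test accuracy", y = "in-weights test accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
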