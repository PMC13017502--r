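# broom-style accessors for fitted objects.

#' @export
tidy.icw_fit <- function(x, ...) {
  if (is.null(x$history)) {
    tibble(step = x$config$steps, loss = mean(utils::tail(x$losses, 100)))
  } else {
    x$history
  }
}

#' @export
glance.icw_fit <- function(x, ...) {
  ev <- evaluate_model(x)
  dplyr::bind_cols(
    tibble(kind = x$spec$kind, steps = x$config$steps,
           n_params = length(x$state$par), seed = x$seed),
    ev
  )
}

#' @export
tidy.icw_sweep <- function(x, ...) x$metrics

#' @export
glance.icw_sweep <- function(x, ...) {
  tidyr::pivot_wider(x$class_shares[, c("learner_class", "share")],
                     names_from = "learner_class", values_from = "share",
                     names_prefix = "share_")
}

#' @export
tidy.icw_curriculum <- function(x, ...) x$metrics

#' @export
glance.icw_curriculum <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_dli = mean(.data$dli),
                     mean_acc_ic = mean(.data$acc_ic),
                     mean_acc_iw = mean(.data$acc_iw), .groups = "drop")
}
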