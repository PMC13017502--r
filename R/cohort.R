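# Synthetic behavioural cohorts and the group-contrast statistics stage:
# logistic/linear regressions with cluster-robust Wald tests,
# BIC-approximated Bayes factors and Bonferroni correction. The cohort
# simulator is the stand-in for human data: each participant is a mixture
# of an in-context rule, in-weights retrieval and lapses.

#' Participant profiles for a synthetic cohort
#'
#' @param groups a data frame with one row per group and columns `group`
#'   (label, e.g. the training `alpha` or a curriculum name), `p_ic`
#'   (probability of applying the in-context rule when available), `p_iw`
#'   (probability of retrieving a trained association) and optionally
#'   `lapse` (uniform-guess probability, default 0).
#' @param n_per_group participants per group.
#' @return a tibble with one row per participant.
#' @export
#' @examples
#' cohort_profiles(data.frame(group = c(0, 4), p_ic = c(0.9, 0.1),
#'                            p_iw = c(0.05, 0.95)), n_per_group = 30)
cohort_profiles <- function(groups, n_per_group = 30) {
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "p_ic", "p_iw") %in% names(groups)))
  if (!"lapse" %in% names(groups)) groups$lapse <- 0
  if (any(groups$p_ic < 0 | groups$p_ic > 1 | groups$p_iw < 0 | groups$p_iw > 1 |
          groups$lapse < 0 | groups$lapse > 1)) {
    abort("profile probabilities must lie in [0, 1]", class = "zipflearn_argument_error")
  }
  out <- tidyr::uncount(groups, weights = n_per_group)
  out$participant_id <- seq_len(nrow(out))
  dplyr::relocate(out, "participant_id")
}

#' Simulate a behavioural cohort
#'
#' Generates per-trial correctness records for every participant across the
#' block structure (training plus the three 30-trial test blocks by
#' default). Response branch logic per trial:
#' \itemize{
#'   \item with probability `lapse` the response is uniform over the `L`
#'     labels (correct with probability `1/L`);
#'   \item otherwise, on in-context blocks the rule is applied with
#'     probability `p_ic`; on in-weights blocks retrieval succeeds with
#'     probability `p_iw`; on training blocks either route suffices;
#'   \item on arbitrage blocks both strategies can fire
#'     (`p_ic`, `p_iw` independently); when both do, the context response
#'     wins with probability `p_ic / (p_ic + p_iw)`.
#' }
#'
#' @param profiles a [cohort_profiles()] tibble (>= 2 groups for contrasts).
#' @param n_train training trials per participant (default 150).
#' @param n_test trials per test block (default 30).
#' @param n_labels label pool size `L`.
#' @param seed integer seed.
#' @param blocks which block kinds to simulate (all four by default).
#' @return a `"cohort_table"` tibble with columns `participant_id`, `group`,
#'   `block_kind`, `trial_index`, `correct` (0/1, `NA` on arbitrage) and
#'   `response_type` (`"context"`, `"trained"`, `"other"`).
#' @export
simulate_cohort <- function(profiles, n_train = 150, n_test = 30, n_labels = 10,
                            seed = 1,
                            blocks = c("train", "ic_test", "iw_test", "arbitrage")) {
  profiles <- as_tibble(profiles)
  if (nrow(profiles) == 0) abort("`profiles` is empty", class = "zipflearn_argument_error")
  L <- n_labels
  counts <- ifelse(blocks == "train", n_train, n_test)
  block_vec <- rep(blocks, counts)
  idx_vec <- unlist(lapply(counts, seq_len), use.names = FALSE)
  nb <- length(block_vec)
  np <- nrow(profiles)
  total <- nb * np

  bl <- rep(block_vec, times = np)
  p_ic <- rep(profiles$p_ic, each = nb)
  p_iw <- rep(profiles$p_iw, each = nb)
  lp <- rep(profiles$lapse, each = nb)

  out <- with_stream(seed, {
    lapse <- runif(total) < lp
    fire_ic <- runif(total) < p_ic
    fire_iw <- runif(total) < p_iw
    guess_ok <- runif(total) < 1 / L
    guess_kind <- sample(c("context", "trained", "other"), total, replace = TRUE,
                         prob = c(1 / L, 1 / L, (L - 2) / L))
    both_ctx <- runif(total) < p_ic / (p_ic + p_iw + 1e-12)
    correct <- dplyr::case_when(
      bl == "arbitrage" ~ NA_integer_,
      lapse ~ as.integer(guess_ok),
      bl == "train" ~ as.integer(fire_ic | fire_iw),
      bl == "ic_test" ~ as.integer(fire_ic),
      TRUE ~ as.integer(fire_iw)
    )
    rtype <- dplyr::case_when(
      lapse ~ guess_kind,
      bl == "ic_test" & fire_ic ~ "context",
      bl == "ic_test" ~ "other",
      bl == "iw_test" & fire_iw ~ "trained",
      bl == "iw_test" ~ "other",
      # train and arbitrage: both strategies may fire
      fire_ic & fire_iw & bl == "arbitrage" ~ ifelse(both_ctx, "context", "trained"),
      fire_ic ~ "context",
      fire_iw ~ "trained",
      TRUE ~ "other"
    )
    tibble(participant_id = rep(profiles$participant_id, each = nb),
           group = rep(profiles$group, each = nb),
           block_kind = bl,
           trial_index = rep(idx_vec, times = np),
           correct = correct, response_type = rtype)
  })
  class(out) <- c("cohort_table", class(out))
  out
}

#' Round-trip a cohort table through CSV
#'
#' @param table a cohort table.
#' @param path file path.
#' @return `write_cohort_csv()` the table invisibly; `read_cohort_csv()` the
#'   re-read table.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(table)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_integer(),
                           block_kind = readr::col_character(),
                           trial_index = readr::col_integer(),
                           correct = readr::col_integer(),
                           response_type = readr::col_character()))
  class(out) <- c("cohort_table", class(out))
  out
}

#' Per-participant strategy summaries and double-learning index
#'
#' @param table a cohort table.
#' @param chance chance level (default `1/10`).
#' @return a tibble with one row per participant: mean accuracies per block
#'   type, arbitrage response shares and `dli`.
#' @export
cohort_summary <- function(table, chance = 0.1) {
  acc <- table |>
    dplyr::filter(.data$block_kind != "arbitrage") |>
    dplyr::group_by(.data$participant_id, .data$group, .data$block_kind) |>
    dplyr::summarise(acc = mean(.data$correct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "block_kind", values_from = "acc",
                       names_prefix = "acc_")
  arb <- table |>
    dplyr::filter(.data$block_kind == "arbitrage") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(arb_p_ic = mean(.data$response_type == "context"),
                     arb_p_iw = mean(.data$response_type == "trained"),
                     .groups = "drop")
  out <- dplyr::left_join(acc, arb, by = "participant_id")
  out$dli <- double_learning_index(out$acc_ic_test, out$acc_iw_test, chance)
  out
}

#' Recover generative strategy probabilities from a cohort
#'
#' Method-of-moments inversion of the branch model: with known lapse rate,
#' `p_ic = (m_ic - lapse/L) / (1 - lapse)` from the in-context block mean
#' (and likewise for `p_iw`).
#'
#' @param table a cohort table.
#' @param lapse assumed lapse rate.
#' @param n_labels label pool size.
#' @return a tibble per participant with `p_ic_hat`, `p_iw_hat`.
#' @export
recover_profiles <- function(table, lapse = 0, n_labels = 10) {
  s <- cohort_summary(table)
  inv <- function(m) pmin(1, pmax(0, (m - lapse / n_labels) / (1 - lapse)))
  tibble(participant_id = s$participant_id, group = s$group,
         p_ic_hat = inv(s$acc_ic_test), p_iw_hat = inv(s$acc_iw_test))
}

#' BIC-approximated Bayes factor
#'
#' `BF = exp((BIC0 - BIC1)/2)`, the evidence for the alternative relative
#' to the null. Interpretation bands: BF > 3 / 10 / 100 are substantial /
#' strong / decisive evidence for an effect; BF < 0.3 / 0.1 / 0.01 the
#' corresponding evidence for its absence.
#'
#' @param bic_null BIC of the null model.
#' @param bic_alt BIC of the model with the effect.
#' @return the Bayes factor with attribute `"category"`.
#' @export
#' @examples
#' bayes_factor(10, 10)                 # 1
#' bayes_factor(2 * log(100), 0)        # 100
bayes_factor <- function(bic_null, bic_alt) {
  stopifnot(is.finite(bic_null), is.finite(bic_alt))
  bf <- exp((bic_null - bic_alt) / 2)
  structure(bf, category = bf_category(bf))
}

#' @rdname bayes_factor
#' @param bf a Bayes factor.
#' @export
bf_category <- function(bf) {
  dplyr::case_when(
    bf > 100 ~ "decisive evidence for effect",
    bf > 10 ~ "strong evidence for effect",
    bf > 3 ~ "substantial evidence for effect",
    bf < 0.01 ~ "decisive evidence for absence",
    bf < 0.1 ~ "strong evidence for absence",
    bf < 0.3 ~ "substantial evidence for absence",
    TRUE ~ "anecdotal"
  )
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @param m number of comparisons (`>=` the number of p values; defaults to
#'   their count).
#' @return adjusted p values `min(1, m * p)`, order preserved.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) {
    abort("p values must lie in [0, 1]", class = "zipflearn_argument_error")
  }
  if (m < length(p_values)) {
    abort("`m` must be at least the number of p values", class = "zipflearn_argument_error")
  }
  pmin(1, m * p_values)
}

#' Group contrast on a cohort block
#'
#' Fits the block's outcome against a group covariate. For
#' `family = "logistic"` the per-trial correctness is modelled by maximum
#' likelihood logistic regression with cluster-robust (participant-level)
#' standard errors and a Wald p value; `family = "linear"` models a
#' per-participant outcome (by default the double-learning index) by
#' ordinary least squares. Both report the BIC of the fitted model and of
#' the intercept-only null at the same grouping structure, and the
#' BIC-approximated Bayes factor. `method = "glmer"` switches to a
#' random-intercept-per-participant logistic mixed model (requires lme4).
#' Perfect separation is detected, flagged, and handled by a light
#' data-augmentation penalty (half a success and half a failure per
#' participant cell).
#'
#' @param table a cohort table (or, for `family = "linear"`, any data frame
#'   with `group` and the outcome column).
#' @param block_kind which block to analyse (`"ic_test"`, `"iw_test"`,
#'   `"train"`, or `"arbitrage"` -- the latter models the share of
#'   context-consistent responses).
#' @param outcome outcome column for the linear family (default `"dli"`,
#'   computed via [cohort_summary()] when absent).
#' @param family `"logistic"` or `"linear"`.
#' @param method `"glm"` (fixed effects + cluster-robust Wald) or
#'   `"glmer"` (random intercept per participant).
#' @return an object of class `"icw_contrast"`.
#' @export
fit_group_contrast <- function(table, block_kind = "ic_test", outcome = "dli",
                               family = c("logistic", "linear"),
                               method = c("glm", "glmer")) {
  family <- match.arg(family)
  method <- match.arg(method)
  gvals <- unique(table$group)
  if (length(gvals) < 2) {
    abort("need >= 2 group levels for a contrast", class = "zipflearn_argument_error")
  }
  gnum <- if (is.numeric(table$group)) table$group else as.numeric(factor(table$group))

  if (family == "linear") {
    df <- if (outcome %in% names(table)) as_tibble(table) else cohort_summary(table)
    df$g <- if (is.numeric(df$group)) df$group else as.numeric(factor(df$group))
    f1 <- lm(df[[outcome]] ~ df$g)
    f0 <- lm(df[[outcome]] ~ 1)
    beta <- coef(summary(f1))[2, 1]
    se <- coef(summary(f1))[2, 2]
    p <- coef(summary(f1))[2, 4]
    bic1 <- BIC(f1); bic0 <- BIC(f0)
    fit <- f1
    separation <- FALSE
  } else {
    df <- table |>
      dplyr::filter(.data$block_kind == !!block_kind)
    if (block_kind == "arbitrage") {
      df$correct <- as.integer(df$response_type == "context")
    }
    df$g <- if (is.numeric(df$group)) df$group else as.numeric(factor(df$group))
    # aggregate to per-participant binomials: same likelihood, faster fits
    agg <- df |>
      dplyr::group_by(.data$participant_id, .data$g) |>
      dplyr::summarise(k = sum(.data$correct), n = dplyr::n(), .groups = "drop")
    # glm warns about separation-driven fitted probabilities and about the
    # fractional pseudo-counts of the penalised refit; both are expected here
    fit1 <- function(a) suppressWarnings(glm(cbind(k, n - k) ~ g,
                                             family = binomial(), data = a))
    fit0 <- function(a) suppressWarnings(glm(cbind(k, n - k) ~ 1,
                                             family = binomial(), data = a))
    f1 <- fit1(agg)
    separation <- any(abs(coef(f1)) > 12) || !f1$converged
    if (separation) {
      aug <- agg
      aug$k <- aug$k + 0.5
      aug$n <- aug$n + 1
      f1 <- fit1(aug)
      f0 <- fit0(aug)
    } else {
      f0 <- fit0(agg)
    }
    if (method == "glmer") {
      if (!requireNamespace("lme4", quietly = TRUE)) {
        abort("method = 'glmer' requires the lme4 package")
      }
      m1 <- lme4::glmer(cbind(k, n - k) ~ g + (1 | participant_id),
                        family = binomial(), data = agg)
      m0 <- lme4::glmer(cbind(k, n - k) ~ 1 + (1 | participant_id),
                        family = binomial(), data = agg)
      sm <- summary(m1)$coefficients
      beta <- sm[2, 1]; se <- sm[2, 2]; p <- sm[2, 4]
      bic1 <- BIC(m1); bic0 <- BIC(m0)
      fit <- m1
    } else {
      vc <- sandwich::vcovCL(f1, cluster = agg$participant_id)
      beta <- coef(f1)[["g"]]
      se <- sqrt(vc["g", "g"])
      p <- 2 * pnorm(-abs(beta / se))
      bic1 <- BIC(f1); bic0 <- BIC(f0)
      fit <- f1
    }
  }
  bf <- bayes_factor(bic0, bic1)
  structure(list(fit = fit, family = family, method = method,
                 block_kind = block_kind, outcome = outcome,
                 beta = unname(beta), se = unname(se), p_value = unname(p),
                 bic = bic1, bic_null = bic0,
                 bf = as.numeric(bf), bf_category = attr(bf, "category"),
                 separation = separation),
            class = "icw_contrast")
}

#' @export
print.icw_contrast <- function(x, ...) {
  cat(sprintf("<icw_contrast> %s on %s: beta = %.3f +/- %.3f, p = %.4g, BF = %.3g (%s)%s\n",
              x$family, if (x$family == "linear") x$outcome else x$block_kind,
              x$beta, x$se, x$p_value, x$bf, x$bf_category,
              if (x$separation) " [separation: penalised fit]" else ""))
  invisible(x)
}

#' @export
tidy.icw_contrast <- function(x, ...) {
  tibble(term = "group", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p_value)
}

#' @export
glance.icw_contrast <- function(x, ...) {
  tibble(family = x$family, block_kind = x$block_kind, BIC = x$bic,
         BIC_null = x$bic_null, bayes_factor = x$bf,
         bf_category = x$bf_category, separation = x$separation)
}

#' Export a contrast fit as JSON
#'
#' @param x an `icw_contrast`.
#' @param path file path.
#' @export
write_contrast_json <- function(x, path) {
  obj <- x[c("family", "method", "block_kind", "outcome", "beta", "se",
             "p_value", "bic", "bic_null", "bf", "bf_category", "separation")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
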