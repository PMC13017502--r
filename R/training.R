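# Training loop: Adam on cross-entropy over the query-position label, fresh
# trial batches sampled every step from the phase-appropriate distribution,
# and (optionally) a fixed probe suite evaluated at regular checkpoints so
# learning trajectories are comparable across a run.

#' Training configuration
#'
#' Defaults follow the study regime: 5,000 steps with batches of 128 trials
#' and Adam at learning rate 0.01 (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
#' Held-out probe sets (1,000 trials per block type) are fixed per run and
#' revisited every `eval_every` steps without gradient updates.
#'
#' @param steps number of optimisation steps.
#' @param batch_size trials per step.
#' @param learning_rate Adam learning rate.
#' @param eval_every checkpoint cadence in steps (`Inf` to evaluate only at
#'   the end).
#' @param probe_n trials per probe block.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param record_min minimum exposures for an item to count as trained.
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(steps = 5000, batch_size = 128, learning_rate = 0.01,
                         eval_every = 100, probe_n = 1000,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         record_min = 2) {
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, eval_every = eval_every,
                 probe_n = as.integer(probe_n), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, record_min = record_min),
            class = "train_config")
}

# marginal pmf of the whole run (phase-length-weighted for curricula)
.run_marginal_pmf <- function(dist, steps) {
  if (inherits(dist, "curriculum_spec")) {
    w <- (dist$phases$to - dist$phases$from + 1) / dist$total_steps
    Reduce(`+`, purrr::map2(dist$phases$alpha, w,
                            function(a, wi) wi * dist_pmf(zipf_spec(a, dist$n_ranks))))
  } else {
    dist_pmf(dist)
  }
}

# chunk boundaries: never cross a curriculum phase edge or a checkpoint
.chunk_plan <- function(steps, eval_every, dist, max_chunk = 100L) {
  edges <- c(0L, steps)
  if (is.finite(eval_every)) edges <- c(edges, seq(0L, steps, by = eval_every))
  if (inherits(dist, "curriculum_spec")) edges <- c(edges, dist$phases$to)
  edges <- sort(unique(pmin(pmax(edges, 0L), steps)))
  out <- list()
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    starts <- seq(a, b - 1L, by = max_chunk)
    for (s0 in starts) {
      out[[length(out) + 1L]] <- c(from = s0 + 1L, to = min(s0 + max_chunk, b))
    }
  }
  out
}

#' Train a learner on a task
#'
#' Trains the model with Adam on cross-entropy at the query position,
#' sampling a fresh batch from the (phase-appropriate) training
#' distribution at every step. Probe evaluations never propagate gradients.
#' A run is reproducible end-to-end from `(spec, dist, config, seed)`:
#' the master seed splits into independent streams for the vocabulary, the
#' rank permutation, the model initialisation, the trial stream and the
#' probe sets.
#'
#' @param spec a [model_spec()].
#' @param dist a [zipf_spec()], [composite_spec()] or [curriculum_spec()]
#'   (ignored when `task` is supplied).
#' @param config a [train_config()].
#' @param seed master seed for the run.
#' @param vocab optional pre-built vocabulary; by default one is built with
#'   `K = dist$n_ranks` items (the full support is the vocabulary).
#' @param task optional pre-built task object ([main_task()] or
#'   [ti_task()]); overrides `dist`/`vocab`/`layout`.
#' @param layout token layout for the main task.
#' @return an object of class `"icw_fit"`: the trained `state`, the probe
#'   `history` tibble (one row per checkpoint), realised `rank_counts`, the
#'   `trained_ranks` record and the run metadata.
#' @export
train_model <- function(spec, dist = NULL, config = train_config(), seed = 1,
                        vocab = NULL, task = NULL, layout = "pair_adjacent") {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "train_config"))
  if (is.null(task)) {
    if (is.null(dist)) abort("supply `dist` or `task`", class = "zipflearn_argument_error")
    if (is.null(vocab)) {
      vocab <- build_vocabulary(K = dist$n_ranks, L = spec$n_outputs,
                                D = spec$d_in - spec$seq_len,
                                seed = derive_seed(seed, "vocab"))
    }
    task <- main_task(vocab, dist, layout = layout,
                      n_context = (spec$seq_len - 1L) %/% 2L,
                      seed = derive_seed(seed, "task"))
  }
  dist <- task$dist
  if (task$seq_len != spec$seq_len || task$d_in != spec$d_in ||
      task$n_outputs != spec$n_outputs) {
    abort("model specification does not match the task geometry",
          class = "zipflearn_argument_error")
  }

  state <- init_model(spec, seed = derive_seed(seed, "init"))
  np <- length(state$par)
  adam <- list(m = numeric(np), v = numeric(np), t = 0L)

  n_ranks <- dist$n_ranks
  total_draws <- config$steps * config$batch_size
  marginal <- .run_marginal_pmf(dist, config$steps)

  # fixed trajectory probes: iw/arbitrage queries restricted to ranks whose
  # expected exposure over the whole run is at least `record_min`
  probes <- NULL
  if (is.finite(config$eval_every)) {
    expected_ranks <- which(marginal * total_draws >= config$record_min)
    if (length(expected_ranks) == 0) expected_ranks <- seq_len(n_ranks)
    probes <- with_stream(derive_seed(seed, "probes"), list(
      train = task_probe(task, "train", config$probe_n),
      ic = task_probe(task, "ic_test", config$probe_n),
      iw = task_probe(task, "iw_test", config$probe_n, record_ranks = expected_ranks),
      arb = task_probe(task, "arbitrage", config$probe_n, record_ranks = expected_ranks)
    ))
  }

  chunks <- .chunk_plan(config$steps, config$eval_every, dist)
  rank_counts <- integer(n_ranks)
  history <- list()
  losses <- numeric(config$steps)

  snapshot <- function(step, loss) {
    st <- state; st$par <- adamize$par
    row <- .probe_metrics(st, probes, task$chance)
    history[[length(history) + 1L]] <<- dplyr::bind_cols(
      tibble(step = step, loss = loss), row)
  }

  adamize <- list(par = state$par)
  trial_seed <- derive_seed(seed, "trials")
  with_stream(trial_seed, {
    if (!is.null(probes)) snapshot(0L, NA_real_)
    for (ch in chunks) {
      S <- ch["to"] - ch["from"] + 1L
      batch <- task_train_batch(task, S * config$batch_size, step = ch["from"])
      if (!is.null(batch$ranks)) {
        rank_counts <- rank_counts + tabulate(batch$ranks, nbins = n_ranks)
      }
      res <- cpp_train_chunk(adamize$par, adam$m, adam$v, adam$t,
                             batch$X, as.integer(batch$y),
                             config$batch_size, as.integer(S), unclass(spec),
                             config$learning_rate, config$beta1, config$beta2,
                             config$adam_eps)
      if (res$nan_at > 0) {
        abort(sprintf("loss became non-finite at step %d", ch["from"] + res$nan_at - 1L),
              class = "zipflearn_nan_loss",
              step = ch["from"] + res$nan_at - 1L, par = res$par)
      }
      adamize$par <- res$par
      adam$m <- res$m; adam$v <- res$v; adam$t <- res$t
      losses[ch["from"]:ch["to"]] <- res$loss
      if (!is.null(probes) && ch["to"] %% config$eval_every == 0) {
        snapshot(as.integer(ch["to"]), mean(res$loss))
      }
    }
  })

  state$par <- adamize$par
  trained_ranks <- which(rank_counts >= config$record_min)
  structure(list(
    state = state, spec = spec, config = config, task = task, dist = dist,
    seed = seed, history = if (length(history)) dplyr::bind_rows(history) else NULL,
    losses = losses, rank_counts = rank_counts, trained_ranks = trained_ranks
  ), class = "icw_fit")
}

# metrics on a fixed probe suite (used for trajectory checkpoints)
.probe_metrics <- function(state, probes, chance) {
  if (is.null(probes)) return(tibble())
  acc <- function(p) mean(.predict_labels(forward(state, p$X)$logits) == p$y)
  a_train <- acc(probes$train)
  a_ic <- acc(probes$ic)
  a_iw <- acc(probes$iw)
  pred <- .predict_labels(forward(state, probes$arb$X)$logits)
  p_ic <- mean(pred == probes$arb$context_label)
  p_iw <- mean(pred == probes$arb$trained_label)
  tibble(acc_train = a_train, acc_ic = a_ic, acc_iw = a_iw,
         arb_p_ic = p_ic, arb_p_iw = p_iw,
         dli = double_learning_index(a_ic, a_iw, chance))
}

#' @export
print.icw_fit <- function(x, ...) {
  cat(sprintf("<icw_fit> %s trained %d steps (seed %s)\n",
              x$spec$kind, x$config$steps, format(x$seed)))
  if (!is.null(x$history)) {
    print(utils::tail(x$history, 1))
  }
  invisible(x)
}

#' Train independent replicate models
#'
#' Replicates share the specification, distribution and configuration but
#' use independent master seeds derived from `seed`, so vocabularies, item
#' permutations, initialisations and trial streams all differ across
#' replicates while the whole population stays reproducible.
#'
#' @inheritParams train_model
#' @param n_models number of replicates.
#' @param keep_models keep the full fit objects (otherwise only evaluation
#'   summaries are retained).
#' @param probe_n probe-set size for the final evaluation.
#' @return a list with `fits` (when `keep_models`) and `metrics`, a tibble
#'   with one row per replicate (accuracies, arbitrage decomposition,
#'   double-learning index and learner class).
#' @export
run_replicates <- function(spec, dist, config = train_config(), n_models = 5,
                           seed = 1, keep_models = FALSE, probe_n = NULL,
                           layout = "pair_adjacent") {
  stopifnot(n_models >= 1)
  probe_n <- probe_n %||% config$probe_n
  rows <- vector("list", n_models)
  fits <- if (keep_models) vector("list", n_models) else NULL
  for (i in seq_len(n_models)) {
    fit <- train_model(spec, dist, config, seed = derive_seed(seed, "replicate", i),
                       layout = layout)
    ev <- evaluate_model(fit, probe_n = probe_n)
    rows[[i]] <- dplyr::bind_cols(tibble(model = i, seed = fit$seed), ev)
    if (keep_models) fits[[i]] <- fit
  }
  out <- list(metrics = dplyr::bind_rows(rows), fits = fits)
  class(out) <- "icw_population"
  out
}

#' @export
print.icw_population <- function(x, ...) {
  cat(sprintf("<icw_population> %d model(s)\n", nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}
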