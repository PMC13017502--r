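# Scoring trained models on the probe blocks, the double-learning index,
# learner classification, and induction-head diagnostics via idealized
# attention templates.

#' Accuracy of a model on a block of trials
#'
#' Scores argmax responses against the block's criterion label: the
#' context-implied label for in-context probes, the trained label for
#' in-weights probes. All trials must be of one kind.
#'
#' @param state a model state.
#' @param trials a list of [make_trial()] objects of a single kind.
#' @param vocab the vocabulary used to build the trials.
#' @param layout token layout.
#' @return the proportion of correct responses.
#' @export
evaluate_block <- function(state, trials, vocab, layout = "pair_adjacent") {
  if (length(trials) < 1) abort("need at least one trial", class = "zipflearn_argument_error")
  kinds <- unique(vapply(trials, `[[`, character(1), "kind"))
  if (length(kinds) != 1) abort("trials must all be of one kind", class = "zipflearn_argument_error")
  if (kinds == "arbitrage") {
    abort("arbitrage blocks have no correct answer; use arbitrage_decompose()",
          class = "zipflearn_argument_error")
  }
  y <- vapply(trials, `[[`, integer(1), "correct_label")
  pred <- vapply(trials, function(tr) {
    predict_labels(state, encode_trial(tr, vocab, layout))
  }, integer(1))
  mean(pred == y)
}

#' Decompose arbitrage responses into strategies
#'
#' On arbitrage probes the context-implied label and the trained label
#' conflict by construction. The decomposition reports the fraction of
#' responses matching each; the remainder (`1 - p_ic - p_iw`) matched
#' neither.
#'
#' @param state a model state.
#' @param trials a list of arbitrage [make_trial()] objects.
#' @param vocab the vocabulary.
#' @param layout token layout.
#' @return a named list with `p_ic` and `p_iw`.
#' @export
arbitrage_decompose <- function(state, trials, vocab, layout = "pair_adjacent") {
  ctx <- vapply(trials, `[[`, integer(1), "context_label_at_target")
  trn <- vapply(trials, `[[`, integer(1), "trained_label")
  if (any(ctx == trn)) {
    abort("arbitrage trials must have distinct context and trained labels",
          class = "zipflearn_invariant_error")
  }
  pred <- vapply(trials, function(tr) {
    predict_labels(state, encode_trial(tr, vocab, layout))
  }, integer(1))
  list(p_ic = mean(pred == ctx), p_iw = mean(pred == trn))
}

#' Double-learning index
#'
#' `D = scale(m_ic) * scale(m_iw)` with `scale(m) = (m - chance)/(1 - chance)`:
#' the product of chance-rescaled in-context and in-weights accuracies. `D`
#' is 1 for perfect dual mastery, 0 whenever either accuracy sits exactly at
#' chance, and can be negative when one accuracy falls below chance.
#'
#' @param m_ic mean in-context test accuracy.
#' @param m_iw mean in-weights test accuracy.
#' @param chance chance level, in `(0, 1)` (default `0.1` for `L = 10`).
#' @return the index (vectorised over its first two arguments).
#' @export
#' @examples
#' double_learning_index(1, 1, 0.1)      # 1
#' double_learning_index(0.1, 0.9, 0.1)  # 0
double_learning_index <- function(m_ic, m_iw, chance = 0.1) {
  if (any(chance <= 0 | chance >= 1)) {
    abort("`chance` must lie strictly between 0 and 1", class = "zipflearn_argument_error")
  }
  sc <- function(m) (m - chance) / (1 - chance)
  sc(m_ic) * sc(m_iw)
}

#' Classify a learner from its two test accuracies
#'
#' @param acc_ic in-context test accuracy.
#' @param acc_iw in-weights test accuracy.
#' @param threshold class boundary (must exceed chance); the default 0.5
#'   separates the empirical clusters cleanly for `L = 10`.
#' @param chance chance level.
#' @return a character vector over `{"in_context", "in_weights", "double",
#'   "neither"}` (vectorised).
#' @export
classify_learner <- function(acc_ic, acc_iw, threshold = 0.5, chance = 0.1) {
  if (any(threshold <= chance)) {
    abort("`threshold` must exceed chance", class = "zipflearn_argument_error")
  }
  ic <- acc_ic > threshold
  iw <- acc_iw > threshold
  dplyr::case_when(ic & iw ~ "double",
                   ic ~ "in_context",
                   iw ~ "in_weights",
                   TRUE ~ "neither")
}

#' Full evaluation of a trained model
#'
#' Builds fresh probe sets (1,000 trials per block by default) from the
#' realised training record of a fit and reports the standard metric suite:
#' train / in-context / in-weights accuracies, the arbitrage decomposition,
#' the double-learning index and the learner class.
#'
#' @param fit an [train_model()] fit.
#' @param probe_n probe trials per block type.
#' @param threshold learner-class boundary, see [classify_learner()].
#' @param seed seed for probe construction (defaults to a stream derived
#'   from the fit's master seed).
#' @return a one-row tibble.
#' @export
evaluate_model <- function(fit, probe_n = 1000, threshold = 0.5, seed = NULL) {
  stopifnot(inherits(fit, "icw_fit"))
  task <- fit$task
  record <- fit$trained_ranks
  if (length(record) == 0) record <- which(fit$rank_counts > 0)
  seed <- seed %||% derive_seed(fit$seed, "final-eval")
  probes <- with_stream(seed, list(
    train = task_probe(task, "train", probe_n),
    ic = task_probe(task, "ic_test", probe_n),
    iw = task_probe(task, "iw_test", probe_n, record_ranks = record),
    arb = task_probe(task, "arbitrage", probe_n, record_ranks = record)
  ))
  row <- .probe_metrics(fit$state, probes, task$chance)
  row$learner_class <- classify_learner(row$acc_ic, row$acc_iw, threshold, task$chance)
  row$chance <- task$chance
  row
}

#' Accuracy of the uniform-over-context-labels policy
#'
#' A degenerate in-context strategy that answers with one of the `N`
#' context labels chosen uniformly at random scores exactly `1/N` on trials
#' whose context labels are all distinct (for the default `N = 7`, about
#' 14.3%, against a baseline of `1/L = 10%`). `analytic = TRUE` returns the
#' closed form; otherwise the policy is simulated on freshly built
#' in-context trials with distinct labels.
#'
#' @param n_context context length `N`.
#' @param n_labels label pool size `L` (labels are drawn without
#'   replacement, so all context labels are distinct; requires `L >= N`).
#' @param n_sim simulated trials (when `analytic = FALSE`).
#' @param analytic return the exact value instead of simulating.
#' @param seed simulation seed.
#' @return the policy's expected accuracy.
#' @export
uniform_context_policy_accuracy <- function(n_context = 7, n_labels = 10,
                                            n_sim = 1e5, analytic = FALSE,
                                            seed = 1) {
  if (analytic) return(1 / n_context)
  stopifnot(n_labels >= n_context)
  with_stream(seed, {
    hits <- vapply(seq_len(n_sim), function(i) {
      labels <- sample.int(n_labels, n_context)      # distinct context labels
      tpos <- sample.int(n_context, 1)
      answer <- labels[sample.int(n_context, 1)]      # the policy's response
      answer == labels[tpos]
    }, logical(1))
    mean(hits)
  })
}

# ---------------------------------------------------------------------------
# idealized attention templates and similarity scores
# ---------------------------------------------------------------------------

# causal mask (lower triangle incl. diagonal) as logical matrix
.causal_mask <- function(T_) {
  outer(seq_len(T_), seq_len(T_), ">=")
}

# row-normalised uniform-causal matrix
.uniform_causal <- function(T_) {
  m <- matrix(0, T_, T_)
  for (i in seq_len(T_)) m[i, seq_len(i)] <- 1 / i
  m
}

#' Idealized attention templates for a trial
#'
#' Builds, for each layer of a two-layer attention circuit, the idealized
#' in-context (induction) and in-weights attention patterns for one trial:
#' \itemize{
#'   \item in-context, layer 1 (binding): each label row attends one-hot to
#'     the item it is bound to under the layout (rows whose bound item lies
#'     after them in the sequence, which can happen under `ring_offset3`,
#'     stay uniform-causal); all other rows are uniform-causal.
#'   \item in-context, layer 2 (match-and-retrieve): the query row attends
#'     one-hot to the target slot's label position; other rows
#'     uniform-causal.
#'   \item in-weights (both layers): uniform-causal everywhere -- the
#'     maximal-entropy pattern of a model that ignores the context
#'     (declared convention).
#' }
#'
#' @param trial a trial with a defined target position (train / ic / arbitrage).
#' @param layout token layout.
#' @return a list with `ic` (list of two `T x T` matrices) and `iw` (same).
#' @export
idealized_templates <- function(trial, layout = "pair_adjacent") {
  stopifnot(inherits(trial, "trial"))
  if (is.na(trial$target_position)) {
    abort("in-context template needs a trial with a target in context",
          class = "zipflearn_argument_error")
  }
  N <- trial$N
  T_ <- 2L * N + 1L
  ic1 <- .uniform_causal(T_)
  for (s in seq_len(N)) {
    lr <- .label_row(s, N, layout)
    ir <- 2L * s - 1L
    if (ir <= lr) {           # binding is only causally possible backwards
      ic1[lr, ] <- 0
      ic1[lr, ir] <- 1
    }
  }
  ic2 <- .uniform_causal(T_)
  tgt_label_row <- .label_row(trial$target_position, N, layout)
  ic2[T_, ] <- 0
  ic2[T_, tgt_label_row] <- 1
  iw <- .uniform_causal(T_)
  list(ic = list(ic1, ic2), iw = list(iw, iw))
}

# cosine over the causally valid entries
.masked_cosine <- function(A, Tm, mask) {
  a <- A[mask]; b <- Tm[mask]
  s <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (s == 0) return(0)
  sum(a * b) / s
}

#' Similarity of observed attention to idealized templates
#'
#' Computes, per layer and head, the cosine similarity between the model's
#' attention pattern (restricted to the causally valid entries) and the
#' idealized in-context and in-weights templates, averaged over a probe set
#' of in-context-style trials. An induction-circuit model scores
#' `sim_ic > sim_iw`; a context-ignoring model the reverse.
#'
#' @param fit a trained [train_model()] fit (attention model).
#' @param n_trials probe trials to average over (>= 1; 100 by default).
#' @param seed probe seed.
#' @return a tibble with columns `layer`, `head`, `sim_ic`, `sim_iw`.
#' @export
template_similarity <- function(fit, n_trials = 100, seed = NULL) {
  stopifnot(inherits(fit, "icw_fit"))
  sp <- fit$spec
  if (!sp$kind %in% c("attn_only", "attn_mlp")) {
    abort("template similarity requires an attention model",
          class = "zipflearn_argument_error")
  }
  task <- fit$task
  seed <- seed %||% derive_seed(fit$seed, "templates")
  probe <- with_stream(seed, task_probe(task, "ic_test", n_trials))
  out <- forward(fit$state, probe$X, want_attn = TRUE)
  T_ <- sp$seq_len
  N <- (T_ - 1L) %/% 2L
  mask <- .causal_mask(T_)
  nl <- sp$n_layers
  nh <- sp$n_heads
  # layer-wise ic templates: binding for the first layer, induction for the
  # last; intermediate layers are compared to the uniform-causal pattern
  dummy <- structure(list(N = N, target_position = 1L), class = "trial")
  res <- expand.grid(layer = seq_len(nl), head = seq_len(nh))
  res$sim_ic <- 0; res$sim_iw <- 0
  uc <- .uniform_causal(T_)
  for (i in seq_len(n_trials)) {
    dummy$target_position <- probe$target_position[i]
    tpl <- idealized_templates(dummy, fit$task$layout)
    for (r in seq_len(nrow(res))) {
      l <- res$layer[r]; h <- res$head[r]
      A <- out$attn[[l]][, , (i - 1L) * nh + h]
      ic_t <- if (l == 1) tpl$ic[[1]] else if (l == nl) tpl$ic[[2]] else uc
      res$sim_ic[r] <- res$sim_ic[r] + .masked_cosine(A, ic_t, mask)
      res$sim_iw[r] <- res$sim_iw[r] + .masked_cosine(A, tpl$iw[[1]], mask)
    }
  }
  res$sim_ic <- res$sim_ic / n_trials
  res$sim_iw <- res$sim_iw / n_trials
  as_tibble(res)
}
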