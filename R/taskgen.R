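# Item-label sequence task: vocabulary construction, trial construction for
# the four block kinds (train / in-context / in-weights / arbitrage),
# encoding into token matrices and a reference decoder.
#
# Internal batch encodings use the token-column layout F x (T * n): column
# (i - 1) * T + t holds token t of trial i, with the first D rows carrying
# content and the remaining T rows the positional one-hot.

#' Build the task vocabulary
#'
#' Draws `K` item vectors and `L` label vectors i.i.d. from a standard
#' Gaussian in `D` dimensions and freezes an arbitrary item-to-label
#' assignment (drawn before any training; every label is used by at least
#' one item).
#'
#' @param K number of items (default `2^14`).
#' @param L number of labels (default 10, `L <= K`).
#' @param D content dimension (default 8).
#' @param seed integer seed; the vocabulary is deterministic given the seed.
#' @return an object of class `"vocabulary"`: a list with elements `items`
#'   (`K x D`), `labels` (`L x D`), `assignment` (integer `K`), `K`, `L`, `D`.
#' @export
#' @examples
#' v <- build_vocabulary(K = 100, L = 10, D = 8, seed = 1)
build_vocabulary <- function(K = 2^14, L = 10, D = 8, seed = 1) {
  if (L > K) abort("`L` must not exceed `K`", class = "zipflearn_argument_error")
  with_stream(seed, {
    items <- matrix(rnorm(K * D), K, D)
    labels <- matrix(rnorm(L * D), L, D)
    assignment <- sample(c(seq_len(L), sample.int(L, K - L, replace = TRUE)))
  })
  structure(list(items = items, labels = labels, assignment = as.integer(assignment),
                 K = as.integer(K), L = as.integer(L), D = as.integer(D), seed = seed),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> K = %d items, L = %d labels, D = %d dims\n", x$K, x$L, x$D))
  invisible(x)
}

# label-row position of context slot s (1-based) under a layout
.label_row <- function(s, N, layout) {
  switch(layout,
    pair_adjacent = 2L * s,
    ring_offset3 = 2L * (((s + 2L) %% N) + 1L),
    abort(sprintf("unknown layout: %s", layout), class = "zipflearn_argument_error")
  )
}

#' Construct a single trial
#'
#' Builds one context-plus-query episode of the item-label task. Kinds:
#' \describe{
#'   \item{train}{query drawn from `dist` (through the rank permutation
#'     `perm`); a copy of the query sits at a uniformly drawn target
#'     position and every context pair carries its item's assigned label.}
#'   \item{ic_test}{query and all context items are novel Gaussian vectors
#'     never present in the vocabulary; context labels are uniform over `L`;
#'     the correct label is the one bound to the target position.}
#'   \item{iw_test}{query is a previously trained item, absent from the
#'     context; context items are novel, labels uniform; the criterion label
#'     is the query's trained assignment.}
#'   \item{arbitrage}{query is a trained item and present in context, but
#'     the label bound to it differs from its trained label; distractor
#'     items are drawn uniformly from the vocabulary.}
#' }
#'
#' @param kind one of `"train"`, `"ic_test"`, `"iw_test"`, `"arbitrage"`.
#' @param vocab a [build_vocabulary()] object.
#' @param dist a [zipf_spec()] or [composite_spec()] over ranks (train and,
#'   optionally, iw/arbitrage query sampling).
#' @param trained_items integer vector of vocabulary items with a training
#'   record (required for `iw_test` / `arbitrage`).
#' @param perm rank-to-item permutation (default identity over `K`).
#' @param n_context context length `N` (default 7).
#' @param distinct_labels if `TRUE`, context labels are drawn without
#'   replacement so all `N` context labels differ (requires `L >= N`).
#' @param seed optional seed.
#' @return an object of class `"trial"`.
#' @export
make_trial <- function(kind = c("train", "ic_test", "iw_test", "arbitrage"),
                       vocab, dist = NULL, trained_items = NULL, perm = NULL,
                       n_context = 7, distinct_labels = FALSE, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(vocab, "vocabulary"))
  N <- as.integer(n_context)
  if (is.null(perm)) perm <- seq_len(vocab$K)
  build <- function() {
    D <- vocab$D; L <- vocab$L
    draw_labels <- function(n) {
      if (distinct_labels) sample.int(L, n) else sample.int(L, n, replace = TRUE)
    }
    if (kind %in% c("iw_test", "arbitrage") && length(trained_items) == 0) {
      abort("no trained items recorded; train first or supply `trained_items`",
            class = "zipflearn_state_error")
    }
    sample_trained <- function() {
      if (!is.null(dist)) {
        inv <- match(trained_items, perm)     # ranks of the trained items
        w <- dist_pmf(dist)[inv]
        trained_items[sample.int(length(trained_items), 1, prob = w)]
      } else {
        trained_items[sample.int(length(trained_items), 1)]
      }
    }
    tr <- list(kind = kind, N = N, D = D, L = L,
               context_items = rep(NA_integer_, N),
               context_content = matrix(NA_real_, N, D),
               context_labels = rep(NA_integer_, N),
               query_item = NA_integer_, query_content = NULL,
               target_position = NA_integer_, correct_label = NA_integer_,
               trained_label = NA_integer_, context_label_at_target = NA_integer_)
    if (kind == "train") {
      if (is.null(dist)) abort("`dist` is required for train trials",
                               class = "zipflearn_argument_error")
      rank <- sample_ranks(dist, 1)
      q <- perm[rank]
      ctx <- sample.int(vocab$K, N, replace = TRUE)
      tpos <- sample.int(N, 1)
      ctx[tpos] <- q
      tr$context_items <- ctx
      tr$context_content <- vocab$items[ctx, , drop = FALSE]
      tr$context_labels <- vocab$assignment[ctx]
      tr$query_item <- q
      tr$query_content <- vocab$items[q, ]
      tr$target_position <- tpos
      tr$correct_label <- vocab$assignment[q]
    } else if (kind == "ic_test") {
      content <- matrix(rnorm(N * D), N, D)
      tpos <- sample.int(N, 1)
      qc <- rnorm(D)
      content[tpos, ] <- qc
      tr$context_content <- content
      tr$context_labels <- draw_labels(N)
      tr$query_content <- qc
      tr$target_position <- tpos
      tr$correct_label <- tr$context_labels[tpos]
    } else if (kind == "iw_test") {
      q <- sample_trained()
      tr$context_content <- matrix(rnorm(N * D), N, D)
      tr$context_labels <- draw_labels(N)
      tr$query_item <- q
      tr$query_content <- vocab$items[q, ]
      tr$trained_label <- vocab$assignment[q]
      tr$correct_label <- tr$trained_label
    } else { # arbitrage
      q <- sample_trained()
      ctx <- sample.int(vocab$K, N, replace = TRUE)
      tpos <- sample.int(N, 1)
      ctx[tpos] <- q
      labs <- draw_labels(N)
      trained_lab <- vocab$assignment[q]
      if (labs[tpos] == trained_lab) {
        labs[tpos] <- sample(setdiff(seq_len(L), trained_lab), 1)
      }
      tr$context_items <- ctx
      tr$context_content <- vocab$items[ctx, , drop = FALSE]
      tr$context_labels <- labs
      tr$query_item <- q
      tr$query_content <- vocab$items[q, ]
      tr$target_position <- tpos
      tr$trained_label <- trained_lab
      tr$context_label_at_target <- labs[tpos]
    }
    structure(tr, class = "trial")
  }
  if (is.null(seed)) build() else with_stream(seed, build())
}

#' Encode a trial into a token matrix
#'
#' Produces the `(2N+1) x (D+P)` token matrix of a trial: an alternating
#' sequence of `N` item tokens and `N` label tokens followed by the query
#' token, with content in the first `D` columns and a positional one-hot in
#' the remaining `P = 2N+1` columns. Under the `pair_adjacent` layout the
#' label of context slot `s` sits at sequence position `2s`; under
#' `ring_offset3` it sits at the label position of slot `((s + 2) mod N) + 1`,
#' mirroring a "+3 steps around the ring" binding rule.
#'
#' @param trial a [make_trial()] object.
#' @param vocab the vocabulary the trial was built from.
#' @param layout `"pair_adjacent"` (default) or `"ring_offset3"`.
#' @return a numeric matrix with `2N+1` rows and `D + 2N + 1` columns.
#' @export
encode_trial <- function(trial, vocab, layout = c("pair_adjacent", "ring_offset3")) {
  layout <- layout[1]
  if (!layout %in% c("pair_adjacent", "ring_offset3")) {
    abort(sprintf("unknown layout: %s", layout), class = "zipflearn_argument_error")
  }
  stopifnot(inherits(trial, "trial"))
  N <- trial$N; D <- trial$D
  T_ <- 2L * N + 1L
  E <- matrix(0, T_, D + T_)
  for (s in seq_len(N)) {
    E[2L * s - 1L, seq_len(D)] <- trial$context_content[s, ]
    r <- .label_row(s, N, layout)
    E[r, seq_len(D)] <- vocab$labels[trial$context_labels[s], ]
  }
  E[T_, seq_len(D)] <- trial$query_content
  E[cbind(seq_len(T_), D + seq_len(T_))] <- 1
  E
}

#' Decode a token matrix back into trial structure
#'
#' Reference decoder used as an oracle for the encoding: recovers the
#' per-slot item contents, the label indices bound to each slot (inverting
#' the layout), the query content and the target position (the context slot
#' whose content equals the query's). Items that match a vocabulary row
#' exactly are reported by index; novel items get `NA`.
#'
#' @inheritParams encode_trial
#' @param encoded a matrix produced by [encode_trial()].
#' @return a list with `context_items`, `context_labels`, `query_item`,
#'   `query_content`, `target_position`.
#' @export
decode_trial <- function(encoded, vocab, layout = c("pair_adjacent", "ring_offset3")) {
  layout <- match.arg(layout)
  T_ <- nrow(encoded)
  N <- (T_ - 1L) %/% 2L
  D <- ncol(encoded) - T_
  # positional block must be the identity
  if (!all(encoded[, D + seq_len(T_)] == diag(T_))) {
    abort("positional block is not one-hot by row", class = "zipflearn_argument_error")
  }
  content <- encoded[, seq_len(D), drop = FALSE]
  match_rows <- function(x, table) {
    key <- function(m) apply(m, 1, function(r) paste(format(r, digits = 17), collapse = "|"))
    match(key(x), key(table))
  }
  items <- match_rows(content[2 * seq_len(N) - 1, , drop = FALSE], vocab$items)
  labs_at_row <- match_rows(content[2 * seq_len(N), , drop = FALSE], vocab$labels)
  # invert layout: label at row 2t belongs to slot s with .label_row(s) == 2t
  slot_of_labelrow <- integer(N)
  for (s in seq_len(N)) slot_of_labelrow[.label_row(s, N, layout) / 2L] <- s
  context_labels <- integer(N)
  context_labels[slot_of_labelrow] <- labs_at_row
  qc <- content[T_, ]
  qmatch <- which(vapply(seq_len(N), function(s) {
    isTRUE(all(content[2 * s - 1, ] == qc))
  }, logical(1)))
  list(context_items = items, context_labels = context_labels,
       query_item = match_rows(matrix(qc, 1), vocab$items),
       query_content = qc,
       target_position = if (length(qmatch)) qmatch[1] else NA_integer_)
}

# ---------------------------------------------------------------------------
# vectorised batch builders (internal)
# ---------------------------------------------------------------------------

# slot_content: list of N matrices (n x D); slot_labels: n x N label indices
# (the label *belonging to* slot s); query_content: n x D
.encode_batch <- function(slot_content, slot_labels, query_content, vocab, layout) {
  N <- length(slot_content)
  n <- nrow(query_content)
  D <- ncol(query_content)
  T_ <- 2L * N + 1L
  X <- matrix(0, D + T_, T_ * n)
  base <- (seq_len(n) - 1L) * T_
  for (s in seq_len(N)) {
    X[seq_len(D), base + (2L * s - 1L)] <- t(slot_content[[s]])
    r <- .label_row(s, N, layout)
    X[seq_len(D), base + r] <- t(vocab$labels[slot_labels[, s], , drop = FALSE])
  }
  X[seq_len(D), base + T_] <- t(query_content)
  for (t in seq_len(T_)) X[D + t, base + t] <- 1
  X
}

# training batch: returns X, y (assigned label of query), ranks
.batch_train <- function(vocab, pmf_cum, perm, n, N, layout) {
  ranks <- findInterval(runif(n), pmf_cum, left.open = TRUE) + 1L
  q <- perm[ranks]
  ctx <- matrix(sample.int(vocab$K, n * N, replace = TRUE), n, N)
  tpos <- sample.int(N, n, replace = TRUE)
  ctx[cbind(seq_len(n), tpos)] <- q
  slot_labels <- matrix(vocab$assignment[ctx], n, N)
  slot_content <- lapply(seq_len(N), function(s) vocab$items[ctx[, s], , drop = FALSE])
  X <- .encode_batch(slot_content, slot_labels, vocab$items[q, , drop = FALSE], vocab, layout)
  list(X = X, y = vocab$assignment[q], ranks = ranks, target_position = tpos)
}

# in-context probes: fully novel items; labels uniform over L
.batch_ic <- function(vocab, n, N, layout, distinct_labels = FALSE) {
  D <- vocab$D
  qc <- matrix(rnorm(n * D), n, D)
  tpos <- sample.int(N, n, replace = TRUE)
  slot_content <- lapply(seq_len(N), function(s) {
    m <- matrix(rnorm(n * D), n, D)
    hit <- tpos == s
    m[hit, ] <- qc[hit, , drop = FALSE]
    m
  })
  if (distinct_labels) {
    slot_labels <- t(replicate(n, sample.int(vocab$L, N)))
  } else {
    slot_labels <- matrix(sample.int(vocab$L, n * N, replace = TRUE), n, N)
  }
  y <- slot_labels[cbind(seq_len(n), tpos)]
  X <- .encode_batch(slot_content, slot_labels, qc, vocab, layout)
  list(X = X, y = y, target_position = tpos)
}

# in-weights probes: trained query, novel context, uniform labels
.batch_iw <- function(vocab, record_pmf_cum, record_items, n, N, layout) {
  D <- vocab$D
  idx <- findInterval(runif(n), record_pmf_cum, left.open = TRUE) + 1L
  q <- record_items[idx]
  slot_content <- lapply(seq_len(N), function(s) matrix(rnorm(n * D), n, D))
  slot_labels <- matrix(sample.int(vocab$L, n * N, replace = TRUE), n, N)
  X <- .encode_batch(slot_content, slot_labels, vocab$items[q, , drop = FALSE], vocab, layout)
  list(X = X, y = vocab$assignment[q])
}

# arbitrage probes: trained query present in context with a conflicting label
.batch_arb <- function(vocab, record_pmf_cum, record_items, n, N, layout) {
  idx <- findInterval(runif(n), record_pmf_cum, left.open = TRUE) + 1L
  q <- record_items[idx]
  ctx <- matrix(sample.int(vocab$K, n * N, replace = TRUE), n, N)
  tpos <- sample.int(N, n, replace = TRUE)
  ctx[cbind(seq_len(n), tpos)] <- q
  slot_labels <- matrix(sample.int(vocab$L, n * N, replace = TRUE), n, N)
  trained_lab <- vocab$assignment[q]
  at_t <- slot_labels[cbind(seq_len(n), tpos)]
  clash <- at_t == trained_lab
  if (any(clash)) {
    # resample conflicting labels from the other L - 1 (cyclic shift keeps
    # the replacement uniform over the remaining labels)
    repl <- (trained_lab[clash] + sample.int(vocab$L - 1L, sum(clash), replace = TRUE) - 1L) %% vocab$L + 1L
    slot_labels[cbind(which(clash), tpos[clash])] <- repl
    at_t[clash] <- repl
  }
  slot_content <- lapply(seq_len(N), function(s) vocab$items[ctx[, s], , drop = FALSE])
  X <- .encode_batch(slot_content, slot_labels, vocab$items[q, , drop = FALSE], vocab, layout)
  list(X = X, trained_label = trained_lab, context_label = at_t, target_position = tpos)
}

# ---------------------------------------------------------------------------
# task objects: bundle vocabulary + distribution + layout for training
# ---------------------------------------------------------------------------

#' Bundle a vocabulary and a training distribution into a task
#'
#' The task object is what [train_model()] consumes: it knows how to sample
#' training batches and how to construct the three probe-set kinds. The rank
#' to item binding is a seeded permutation per task, so the "frequent" items
#' differ across replicate runs.
#'
#' @param vocab a [build_vocabulary()] object.
#' @param dist a [zipf_spec()], [composite_spec()] or [curriculum_spec()].
#' @param layout token layout, see [encode_trial()].
#' @param n_context context length `N` (default 7).
#' @param seed seed for the rank-to-item permutation.
#' @return an object of class `"main_task"`.
#' @export
main_task <- function(vocab, dist, layout = "pair_adjacent", n_context = 7, seed = 1) {
  stopifnot(inherits(vocab, "vocabulary"), inherits(dist, "dist_spec"))
  n_ranks <- dist$n_ranks
  if (n_ranks > vocab$K) {
    abort("distribution support exceeds vocabulary size", class = "zipflearn_argument_error")
  }
  perm <- with_stream(derive_seed(seed, "rank-perm"), sample.int(vocab$K, n_ranks))
  N <- as.integer(n_context)
  structure(list(vocab = vocab, dist = dist, layout = layout, perm = perm,
                 N = N, seq_len = 2L * N + 1L, d_in = vocab$D + 2L * N + 1L,
                 n_outputs = vocab$L, chance = 1 / vocab$L, seed = seed),
            class = c("main_task", "zl_task"))
}

# pmf (cumulative) for the distribution in force at training step `step`
.task_step_pmf <- function(task, step) {
  d <- task$dist
  if (inherits(d, "curriculum_spec")) d <- phase_distribution(step, d)
  p <- dist_pmf(d)
  cum <- cumsum(p)
  cum[length(cum)] <- 1
  cum
}

# the distribution used for iw/arbitrage query sampling: the skewed
# component for composite/curriculum training, the distribution itself
# otherwise (test queries come "from the same Zipfian distribution as the
# training")
.task_query_dist <- function(task) {
  d <- task$dist
  if (inherits(d, "composite_spec")) return(zipf_spec(d$alpha_skewed, d$n_ranks))
  if (inherits(d, "curriculum_spec")) {
    a <- max(d$phases$alpha)
    return(zipf_spec(if (a > 0) a else 0, d$n_ranks))
  }
  d
}

# restricted (renormalised) query pmf over a record of trained ranks;
# returns NULL when the record is empty
.record_sampler <- function(task, record_ranks) {
  if (length(record_ranks) == 0) return(NULL)
  qd <- .task_query_dist(task)
  w <- dist_pmf(qd)[record_ranks]
  cum <- cumsum(w / sum(w))
  cum[length(cum)] <- 1
  list(cum = cum, items = task$perm[record_ranks])
}

# generic task interface consumed by train_model(); implemented by
# main_task (here) and ti_task (transitive-inference module)
task_train_batch <- function(task, n, step) UseMethod("task_train_batch")
task_probe <- function(task, kind, n, record_ranks = NULL, ...) UseMethod("task_probe")

#' @export
task_train_batch.main_task <- function(task, n, step) {
  .batch_train(task$vocab, .task_step_pmf(task, step), task$perm, n, task$N, task$layout)
}

#' @export
task_probe.main_task <- function(task, kind, n, record_ranks = NULL,
                                 distinct_labels = FALSE, ...) {
  if (kind == "train") {
    # held-out trials from the stationary training distribution (for
    # curricula: the full mixture across phases, approximated by the
    # composite of its phases in equal proportion)
    d <- task$dist
    if (inherits(d, "curriculum_spec")) {
      alphas <- d$phases$alpha
      pmf <- Reduce(`+`, lapply(alphas, function(a) dist_pmf(zipf_spec(a, d$n_ranks)))) / length(alphas)
      cum <- cumsum(pmf); cum[length(cum)] <- 1
    } else {
      cum <- .task_step_pmf(task, 1L)
    }
    return(.batch_train(task$vocab, cum, task$perm, n, task$N, task$layout))
  }
  if (kind == "ic_test") {
    return(.batch_ic(task$vocab, n, task$N, task$layout, distinct_labels))
  }
  rs <- .record_sampler(task, record_ranks)
  if (is.null(rs)) {
    abort("no trained items recorded yet; cannot build in-weights/arbitrage probes",
          class = "zipflearn_state_error")
  }
  if (kind == "iw_test") {
    .batch_iw(task$vocab, rs$cum, rs$items, n, task$N, task$layout)
  } else if (kind == "arbitrage") {
    .batch_arb(task$vocab, rs$cum, rs$items, n, task$N, task$layout)
  } else {
    abort(sprintf("unknown probe kind: %s", kind), class = "zipflearn_argument_error")
  }
}

#' Export a set of trials to a tidy tibble
#'
#' One row per trial with the query, target position, correct label and the
#' context pairs flattened into `item<i>` / `label<i>` columns; suitable for
#' CSV export with [readr::write_csv()].
#'
#' @param trials a list of [make_trial()] objects.
#' @return a tibble.
#' @export
trials_to_tibble <- function(trials) {
  purrr::map_dfr(trials, function(tr) {
    row <- tibble(kind = tr$kind,
                  query_item = tr$query_item,
                  target_position = tr$target_position,
                  correct_label = tr$correct_label,
                  trained_label = tr$trained_label,
                  context_label_at_target = tr$context_label_at_target)
    for (s in seq_len(tr$N)) {
      row[[paste0("item", s)]] <- tr$context_items[s]
      row[[paste0("label", s)]] <- tr$context_labels[s]
    }
    row
  })
}
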