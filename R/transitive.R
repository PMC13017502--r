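# Transitive-inference variant: ranked six-image environments, contexts of
# ten one-step comparisons, and queries requiring a two-step inference.
# Relation symbols '>' and '<' are two extra Gaussian content vectors; the
# learner classifies between them at the query (L = 2, chance 0.5).

#' Create a transitive-inference environment
#'
#' An environment holds six unique Gaussian image vectors, each with an
#' implicit rank 1..6 (drawn as a random permutation).
#'
#' @param D content dimension.
#' @param seed integer seed (deterministic environments).
#' @param env_id optional identifier.
#' @return an object of class `"ti_environment"` with `images` (`6 x D`,
#'   row `r` = the image of rank `r`) and `ranks` (the permutation mapping
#'   image slots to ranks).
#' @export
make_ti_environment <- function(D = 8, seed = 1, env_id = NA_integer_) {
  with_stream(seed, {
    raw <- matrix(rnorm(6 * D), 6, D)
    ranks <- sample.int(6)
  })
  # store images sorted by rank for convenient pair lookup
  images <- raw[order(ranks), , drop = FALSE]
  structure(list(env_id = env_id, images = images, ranks = ranks, D = D),
            class = "ti_environment")
}

#' @export
print.ti_environment <- function(x, ...) {
  cat(sprintf("<ti_environment> id %s, 6 ranked images (D = %d)\n",
              format(x$env_id), x$D))
  invisible(x)
}

# 10 one-step comparisons covering all 5 adjacent pairs at least once
.ti_context_pairs <- function(n_triplets = 10) {
  repeat {
    p <- sample.int(5, n_triplets, replace = TRUE)
    if (length(unique(p)) == 5) return(sample(p))   # shuffled presentation
  }
}

#' Construct a transitive-inference trial
#'
#' Context: ten one-step comparisons between adjacent ranks of one
#' environment, each rendered canonically as `higher > lower`, sampled with
#' replacement under the guarantee that all five adjacent pairs appear.
#' Query: a pair at rank distance exactly 2. Kinds mirror the main task:
#' `train` and `ic_test` contexts are transitively consistent with the
#' environment (`ic_test` uses a novel environment); `iw_test` presents a
#' trained query pair inside a novel environment's context; `arbitrage`
#' reuses a trained environment with every comparison's relation reversed
#' (`higher < lower`), so the context implies the opposite of the trained
#' relation.
#'
#' @param kind trial kind.
#' @param env_pool list of [make_ti_environment()] objects.
#' @param dist optional [zipf_spec()] over environments (train sampling and
#'   trained-environment weighting).
#' @param trained_envs indices of environments with a training record
#'   (required for `iw_test` / `arbitrage`).
#' @param seed optional seed.
#' @return an object of class `"ti_trial"`.
#' @export
make_ti_trial <- function(kind = c("train", "ic_test", "iw_test", "arbitrage"),
                          env_pool, dist = NULL, trained_envs = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (length(env_pool) == 0) abort("`env_pool` is empty", class = "zipflearn_argument_error")
  build <- function() {
    if (kind %in% c("iw_test", "arbitrage") && length(trained_envs) == 0) {
      abort("no trained environments recorded", class = "zipflearn_state_error")
    }
    pick_trained <- function() {
      if (!is.null(dist)) {
        w <- dist_pmf(dist)[trained_envs]
        trained_envs[sample.int(length(trained_envs), 1, prob = w)]
      } else trained_envs[sample.int(length(trained_envs), 1)]
    }
    novel_env <- function() make_ti_environment(env_pool[[1]]$D,
                                                seed = sample.int(2^30, 1),
                                                env_id = NA_integer_)
    qlo <- sample.int(4, 1)                  # query pair: ranks (qlo, qlo + 2)
    flip <- runif(1) < 0.5
    qpair <- if (flip) c(qlo, qlo + 2L) else c(qlo + 2L, qlo)
    true_sym <- if (qpair[1] > qpair[2]) ">" else "<"
    if (kind == "train") {
      if (is.null(dist)) abort("`dist` required for train trials", class = "zipflearn_argument_error")
      e_idx <- sample_ranks(dist, 1)
      env <- env_pool[[e_idx]]
      list(kind = kind, env_id = e_idx, context_env = env,
           pairs = .ti_context_pairs(), reversed = FALSE,
           query_ranks = qpair, query_content = env$images[qpair, , drop = FALSE],
           correct_symbol = true_sym, trained_symbol = NA_character_,
           context_symbol = true_sym)
    } else if (kind == "ic_test") {
      env <- novel_env()
      list(kind = kind, env_id = NA_integer_, context_env = env,
           pairs = .ti_context_pairs(), reversed = FALSE,
           query_ranks = qpair, query_content = env$images[qpair, , drop = FALSE],
           correct_symbol = true_sym, trained_symbol = NA_character_,
           context_symbol = true_sym)
    } else if (kind == "iw_test") {
      e_idx <- pick_trained()
      tr_env <- env_pool[[e_idx]]
      env <- novel_env()
      list(kind = kind, env_id = e_idx, context_env = env,
           pairs = .ti_context_pairs(), reversed = FALSE,
           query_ranks = qpair, query_content = tr_env$images[qpair, , drop = FALSE],
           correct_symbol = true_sym, trained_symbol = true_sym,
           context_symbol = NA_character_)
    } else {
      e_idx <- pick_trained()
      env <- env_pool[[e_idx]]
      rev_sym <- if (true_sym == ">") "<" else ">"
      list(kind = kind, env_id = e_idx, context_env = env,
           pairs = .ti_context_pairs(), reversed = TRUE,
           query_ranks = qpair, query_content = env$images[qpair, , drop = FALSE],
           correct_symbol = NA_character_, trained_symbol = true_sym,
           context_symbol = rev_sym)
    }
  }
  tr <- if (is.null(seed)) build() else with_stream(seed, build())
  structure(tr, class = "ti_trial")
}

#' Transitive-closure oracle for a trial's context
#'
#' Applies brute-force transitive closure over the relations asserted in
#' the context (as presented, including reversed arbitrage contexts) and
#' answers the query from the closure. On train and in-context trials the
#' oracle always recovers the correct symbol.
#'
#' @param trial a [make_ti_trial()] object.
#' @return `">"`, `"<"` or `NA` if the closure does not order the query pair.
#' @export
ti_closure_oracle <- function(trial) {
  stopifnot(inherits(trial, "ti_trial"))
  # asserted relations: pair p is (hi = p + 1, lo = p); canonical rendering
  # asserts hi > lo, reversed contexts assert hi < lo
  gt <- matrix(FALSE, 6, 6)   # gt[a, b]: context asserts rank-slot a > b
  for (p in trial$pairs) {
    hi <- p + 1L; lo <- p
    if (!trial$reversed) gt[hi, lo] <- TRUE else gt[lo, hi] <- TRUE
  }
  for (k in 1:6) for (a in 1:6) for (b in 1:6) {
    if (gt[a, k] && gt[k, b]) gt[a, b] <- TRUE
  }
  q <- trial$query_ranks
  if (gt[q[1], q[2]]) ">" else if (gt[q[2], q[1]]) "<" else NA_character_
}

#' Bundle a pool of environments into a transitive-inference task
#'
#' @param n_envs number of training environments (the Zipf support).
#' @param alpha Zipfian exponent over environment frequencies.
#' @param D image dimension.
#' @param seed master seed (environments, relation-symbol vectors, rank
#'   permutation).
#' @return an object of class `c("ti_task", "zl_task")`.
#' @export
ti_task <- function(n_envs = 1000, alpha = 0, D = 8, seed = 1) {
  dist <- zipf_spec(alpha, n_envs)
  envs <- lapply(seq_len(n_envs), function(i) {
    make_ti_environment(D, seed = derive_seed(seed, "ti-env", i), env_id = i)
  })
  syms <- with_stream(derive_seed(seed, "ti-symbols"), matrix(rnorm(2 * D), 2, D))
  perm <- with_stream(derive_seed(seed, "ti-perm"), sample.int(n_envs))
  T_ <- 32L
  structure(list(envs = envs, syms = syms, dist = dist, perm = perm,
                 D = as.integer(D), n_triplets = 10L,
                 seq_len = T_, d_in = as.integer(D + T_), n_outputs = 2L,
                 chance = 0.5, seed = seed),
            class = c("ti_task", "zl_task"))
}

# encode a batch of TI trials given per-trial environment image matrices
# (list over trials is too slow; everything here is index-vectorised)
# img_by_rank: (6*n) x D matrix, rows (i-1)*6 + rank = image of that rank for
# trial i's CONTEXT env; q_content: n x 2D (the two query images, possibly
# from a different env); pairs: n x 10 adjacent-pair ids; reversed: length-n
# logical; returns F x (32 n)
.ti_encode <- function(task, img_by_rank, pairs, reversed, q_content) {
  n <- nrow(pairs)
  D <- task$D
  T_ <- task$seq_len
  X <- matrix(0, task$d_in, T_ * n)
  base <- (seq_len(n) - 1L) * T_
  row6 <- (seq_len(n) - 1L) * 6L
  sym_gt <- task$syms[1, ]; sym_lt <- task$syms[2, ]
  for (j in seq_len(task$n_triplets)) {
    p <- pairs[, j]
    hi <- img_by_rank[row6 + p + 1L, , drop = FALSE]
    lo <- img_by_rank[row6 + p, , drop = FALSE]
    c0 <- base + 3L * (j - 1L)
    X[seq_len(D), c0 + 1L] <- t(hi)
    X[seq_len(D), c0 + 3L] <- t(lo)
    sym <- matrix(rep(sym_gt, n), n, D, byrow = TRUE)
    sym[reversed, ] <- matrix(rep(sym_lt, sum(reversed)), sum(reversed), D, byrow = TRUE)
    X[seq_len(D), c0 + 2L] <- t(sym)
  }
  X[seq_len(D), base + 31L] <- t(q_content[, seq_len(D), drop = FALSE])
  X[seq_len(D), base + 32L] <- t(q_content[, D + seq_len(D), drop = FALSE])
  for (t in seq_len(T_)) X[task$D + t, base + t] <- 1
  X
}

# stacked rank-sorted image matrix for a set of environment indices
.ti_images_of <- function(task, env_idx) {
  do.call(rbind, lapply(env_idx, function(e) task$envs[[e]]$images))
}

# fresh novel environments (images only), stacked
.ti_novel_images <- function(task, n) {
  matrix(rnorm(n * 6 * task$D), n * 6, task$D)
}

# coverage-guaranteed context pairs for n trials
.ti_pairs_mat <- function(n, n_triplets = 10) {
  m <- matrix(sample.int(5, n * n_triplets, replace = TRUE), n, n_triplets)
  bad <- which(apply(m, 1, function(r) length(unique(r))) < 5)
  while (length(bad)) {
    m[bad, ] <- matrix(sample.int(5, length(bad) * n_triplets, replace = TRUE),
                       length(bad), n_triplets)
    bad <- bad[apply(m[bad, , drop = FALSE], 1, function(r) length(unique(r))) < 5]
  }
  m
}

# query pairs at rank distance 2; returns list(ranks = n x 2, y = 1/2)
# y = 1 codes '>' (first image outranks second), y = 2 codes '<'
.ti_queries <- function(n) {
  qlo <- sample.int(4, n, replace = TRUE)
  flip <- runif(n) < 0.5
  first <- ifelse(flip, qlo, qlo + 2L)
  second <- ifelse(flip, qlo + 2L, qlo)
  list(ranks = cbind(first, second), y = ifelse(first > second, 1L, 2L))
}

# gather query image content (n x 2D) from a stacked rank-sorted matrix
.ti_query_content <- function(img_by_rank, qranks) {
  n <- nrow(qranks)
  row6 <- (seq_len(n) - 1L) * 6L
  cbind(img_by_rank[row6 + qranks[, 1], , drop = FALSE],
        img_by_rank[row6 + qranks[, 2], , drop = FALSE])
}

#' @export
task_train_batch.ti_task <- function(task, n, step) {
  cum <- cumsum(dist_pmf(task$dist)); cum[length(cum)] <- 1
  ranks <- findInterval(runif(n), cum, left.open = TRUE) + 1L
  env_idx <- task$perm[ranks]
  imgs <- .ti_images_of(task, env_idx)
  pairs <- .ti_pairs_mat(n, task$n_triplets)
  q <- .ti_queries(n)
  X <- .ti_encode(task, imgs, pairs, rep(FALSE, n), .ti_query_content(imgs, q$ranks))
  list(X = X, y = q$y, ranks = ranks)
}

#' @export
task_probe.ti_task <- function(task, kind, n, record_ranks = NULL, ...) {
  pairs <- .ti_pairs_mat(n, task$n_triplets)
  q <- .ti_queries(n)
  if (kind == "train") {
    return(task_train_batch.ti_task(task, n, 1L))
  }
  if (kind == "ic_test") {
    imgs <- .ti_novel_images(task, n)
    X <- .ti_encode(task, imgs, pairs, rep(FALSE, n), .ti_query_content(imgs, q$ranks))
    return(list(X = X, y = q$y))
  }
  if (length(record_ranks) == 0) {
    abort("no trained environments recorded", class = "zipflearn_state_error")
  }
  w <- dist_pmf(task$dist)[record_ranks]
  cum <- cumsum(w / sum(w)); cum[length(cum)] <- 1
  ranks <- record_ranks[findInterval(runif(n), cum, left.open = TRUE) + 1L]
  env_idx <- task$perm[ranks]
  tr_imgs <- .ti_images_of(task, env_idx)
  if (kind == "iw_test") {
    ctx_imgs <- .ti_novel_images(task, n)
    X <- .ti_encode(task, ctx_imgs, pairs, rep(FALSE, n),
                    .ti_query_content(tr_imgs, q$ranks))
    return(list(X = X, y = q$y))
  }
  if (kind == "arbitrage") {
    X <- .ti_encode(task, tr_imgs, pairs, rep(TRUE, n),
                    .ti_query_content(tr_imgs, q$ranks))
    # context asserts the reverse of the trained relation
    return(list(X = X, trained_label = q$y, context_label = 3L - q$y))
  }
  abort(sprintf("unknown probe kind: %s", kind), class = "zipflearn_argument_error")
}
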