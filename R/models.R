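# Learner specifications and states. The default learner is a two-layer
# attention-only transformer: one causal attention head per layer with
# query/key projections of width D_M = 16 over the raw (D+P)-dimensional
# token stream, one combined value/output matrix per layer, residual
# connections, and a classifier of two ReLU layers (D_M units each)
# followed by a linear map to the L outputs.
# The attn_mlp variant interleaves a feed-forward block (two dense D_M
# layers, ReLU), a residual connection and layer normalisation after each
# attention layer. MLP and LSTM baselines are width-matched so their total
# parameter count stays within 10% of the transformer's.

#' Learner specification
#'
#' @param kind `"attn_only"` (default), `"attn_mlp"`, `"mlp"`, `"lstm"` or
#'   `"lstm_query_first"` (an LSTM that reads the query token first).
#' @param n_layers number of attention (or LSTM) layers; for `"mlp"` the
#'   number of hidden layers is fixed at two.
#' @param n_heads causal attention heads per layer (must divide `d_model`).
#' @param d_model intrinsic model dimension `D_M` (default 16); for the
#'   baselines this is the hidden width, chosen automatically (when `NULL`)
#'   to match the default transformer's parameter count within 10%.
#' @param n_outputs number of output classes `L` (default 10).
#' @param d_in input token dimension `D + P` (default `8 + 15 = 23`).
#' @param seq_len sequence length `2N + 1` (default 15).
#' @param score_scale attention score scaling; `NULL` (the default) uses
#'   the standard `1/sqrt(D_M / n_heads)`.
#' @param residual keep residual connections around each attention block
#'   (default `TRUE`).
#' @param values value-pathway parameterisation of each attention layer:
#'   `"single"` (default) learns one combined value/output matrix per layer
#'   (the standard combined-OV form of minimal induction circuits);
#'   `"identity"` learns only query/key projections and adds the raw
#'   attention-weighted stream back; `"learned"` uses separate value and
#'   output projections.
#' @param embed if `TRUE`, a learned linear embedding maps tokens to a
#'   `D_M`-wide residual stream before layer 1; if `FALSE` (the default for
#'   attention-only models), the stream stays at the raw token width `D + P`
#'   and only the query/key projections live in `D_M` dimensions, which
#'   preserves the one-hot positional code in the stream. The `attn_mlp`
#'   variant always embeds.
#' @return an object of class `"model_spec"`.
#' @export
#' @examples
#' model_spec()                      # the default two-layer transformer
#' model_spec("mlp")                 # parameter-matched feed-forward baseline
model_spec <- function(kind = c("attn_only", "attn_mlp", "mlp", "lstm", "lstm_query_first"),
                       n_layers = 2, n_heads = 1, d_model = NULL,
                       n_outputs = 10, d_in = 23, seq_len = 15,
                       score_scale = NULL, residual = TRUE, embed = FALSE,
                       values = c("single", "identity", "learned")) {
  kind <- match.arg(kind)
  values <- match.arg(values)
  if (kind == "attn_mlp") embed <- TRUE   # interleaved blocks run at D_M width
  if (kind %in% c("attn_only", "attn_mlp")) {
    d_model <- d_model %||% 16L
    if (d_model %% n_heads != 0) {
      abort("`d_model` must be divisible by `n_heads`", class = "zipflearn_argument_error")
    }
  }
  sp <- structure(
    list(kind = kind, n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         width = if (is.null(d_model)) NA_integer_ else as.integer(d_model),
         n_outputs = as.integer(n_outputs), d_in = as.integer(d_in),
         seq_len = as.integer(seq_len),
         score_scale = score_scale, residual = isTRUE(residual),
         embed = isTRUE(embed),
         value_mode = match(values, c("identity", "single", "learned")) - 1L),
    class = "model_spec")
  if (is.na(sp$width)) sp$width <- .matched_width(sp)
  if (sp$width < 1) abort("model width must be >= 1", class = "zipflearn_argument_error")
  sp
}

# reference parameter count the baselines are matched against: the default
# transformer at the same input geometry
.reference_count <- function(sp) {
  ref <- sp
  ref$kind <- "attn_only"
  ref$width <- 16L
  ref$n_layers <- 2L
  ref$n_heads <- 1L
  n_params(ref)
}

.matched_width <- function(sp) {
  target <- .reference_count(sp)
  widths <- 1:256
  counts <- vapply(widths, function(w) {
    s2 <- sp; s2$width <- as.integer(w)
    n_params(s2)
  }, numeric(1))
  widths[which.min(abs(counts - target))]
}

#' Number of trainable parameters of a specification
#'
#' @param spec a [model_spec()].
#' @return integer parameter count.
#' @export
n_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  cpp_n_params(unclass(spec))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d layer(s), %d head(s), width %d, %d outputs (%d params)\n",
              x$kind, x$n_layers, x$n_heads, x$width, x$n_outputs, n_params(x)))
  invisible(x)
}

#' Initialise a learner
#'
#' Weights are drawn from centred Gaussians with standard deviation
#' `1/sqrt(fan_in)`; biases start at zero except the LSTM forget-gate bias
#' (set to 1, the standard stabilising choice) and the layer-norm gain (1).
#' Given the same seed the parameters are bitwise identical.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return an object of class `"model_state"`: `spec`, `par` (numeric
#'   vector), `init_seed`.
#' @export
init_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  par <- with_stream(seed, .init_par(spec))
  stopifnot(length(par) == n_params(spec))
  structure(list(spec = spec, par = par, init_seed = seed), class = "model_state")
}

.init_par <- function(sp) {
  M <- sp$width; F <- sp$d_in; L <- sp$n_outputs; T_ <- sp$seq_len
  wmat <- function(nr, nc, fan_in) rnorm(nr * nc, sd = 1 / sqrt(fan_in))
  if (sp$kind %in% c("attn_only", "attn_mlp")) {
    S <- if (sp$embed) M else F
    p <- if (sp$embed) c(wmat(M, F, F), numeric(M)) else numeric(0)
    for (l in seq_len(sp$n_layers)) {
      # query/key projections start small (0.3/sqrt(fan_in)): near-uniform
      # initial attention, so the score pathway sharpens only where the
      # data demand it
      p <- c(p, 0.3 * wmat(M, S, S), 0.3 * wmat(M, S, S))
      if (sp$value_mode >= 1) p <- c(p, wmat(S, S, S))
      if (sp$value_mode >= 2) p <- c(p, wmat(S, S, S))
      if (sp$kind == "attn_mlp") {
        p <- c(p, wmat(S, S, S), numeric(S), wmat(S, S, S), numeric(S),
               rep(1, S), numeric(S))
      }
    }
    c(p, wmat(M, S, S), numeric(M), wmat(M, M, M), numeric(M), wmat(L, M, M), numeric(L))
  } else if (sp$kind == "mlp") {
    FT <- F * T_
    c(wmat(M, FT, FT), numeric(M), wmat(M, M, M), numeric(M), wmat(L, M, M), numeric(L))
  } else {
    H <- M
    p <- numeric(0)
    for (l in seq_len(sp$n_layers)) {
      fin <- if (l == 1) F else H
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1   # forget-gate bias
      p <- c(p, wmat(4 * H, fin, fin), wmat(4 * H, H, H), b)
    }
    c(p, wmat(L, H, H), numeric(L))
  }
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> %s (%d params, init seed %d)\n",
              x$spec$kind, length(x$par), x$init_seed))
  invisible(x)
}

# reorder token columns so the query token comes first (query-first LSTM)
.query_first_X <- function(X, T_) {
  n <- ncol(X) / T_
  ord <- as.vector(vapply(seq_len(n), function(i) {
    base <- (i - 1L) * T_
    base + c(T_, seq_len(T_ - 1L))
  }, integer(T_)))
  X[, ord, drop = FALSE]
}

#' Forward pass of a learner
#'
#' Computes output logits (and, for attention models, the per-layer causal
#' attention patterns) for a batch of encoded sequences. The MLP baseline
#' consumes the sequence flattened into one vector; the query-first LSTM
#' reads the query token before the context.
#'
#' @param state a [init_model()] or trained model state.
#' @param X either a single encoded trial (a `seq_len x d_in` matrix from
#'   [encode_trial()]) or an internal batch matrix of `d_in` rows and
#'   `seq_len * n` token columns.
#' @param want_attn return attention traces (attention models only).
#' @param want_hidden return the final-layer token representations.
#' @return a list with `logits` (`n x L` matrix), and optionally `attn`
#'   (list over layers of `T x T x (n * n_heads)` arrays, rows = attending
#'   position) and `hidden`.
#' @export
forward <- function(state, X, want_attn = FALSE, want_hidden = FALSE) {
  stopifnot(inherits(state, "model_state"))
  sp <- state$spec
  if (nrow(X) == sp$seq_len && ncol(X) == sp$d_in) X <- t(X)  # single trial
  if (nrow(X) != sp$d_in || ncol(X) %% sp$seq_len != 0) {
    abort("input shape does not match the model specification",
          class = "zipflearn_argument_error")
  }
  if (sp$kind == "lstm_query_first") X <- .query_first_X(X, sp$seq_len)
  out <- cpp_forward(state$par, X, unclass(sp), want_attn, want_hidden)
  res <- list(logits = t(out$logits))
  if (want_attn && !is.null(out$attn)) res$attn <- out$attn
  if (want_hidden && !is.null(out$hidden)) res$hidden <- out$hidden
  res
}

# deterministic argmax over logits: lowest index wins ties
.predict_labels <- function(logits) {
  max.col(logits, ties.method = "first")
}

#' Predicted labels for a batch
#'
#' Argmax over output logits with lowest-index tie-breaking.
#'
#' @inheritParams forward
#' @return integer vector of 1-based label predictions.
#' @export
predict_labels <- function(state, X) {
  .predict_labels(forward(state, X)$logits)
}

# flat-parameter layout of the attention models (mirrors the C++ kernel)
.tf_layout <- function(sp) {
  M <- sp$width; F <- sp$d_in; L <- sp$n_outputs
  mlp <- sp$kind == "attn_mlp"
  o <- 0
  take <- function(n) { r <- o + seq_len(n); o <<- o + n; r }
  lay <- list(We = take(M * F), be = take(M), layers = vector("list", sp$n_layers))
  for (l in seq_len(sp$n_layers)) {
    li <- list(Wq = take(M * M), Wk = take(M * M))
    if (sp$value_mode >= 1) li <- c(li, list(Wv = take(M * M)))
    if (sp$value_mode >= 2) li <- c(li, list(Wo = take(M * M)))
    if (mlp) {
      li <- c(li, list(W1 = take(M * M), b1 = take(M), W2 = take(M * M), b2 = take(M),
                       lg = take(M), lb = take(M)))
    }
    lay$layers[[l]] <- li
  }
  lay$Wc1 <- take(M * M); lay$bc1 <- take(M)
  lay$Wc2 <- take(M * M); lay$bc2 <- take(M)
  lay$Wc3 <- take(L * M); lay$bc3 <- take(L)
  lay
}

#' Apply the interleaved feed-forward block of an `attn_mlp` layer
#'
#' Runs the post-attention feed-forward block of the given layer on a set of
#' token representations: two dense `D_M`-unit layers with ReLU, a residual
#' connection and layer normalisation. With all block weights at zero the
#' output is the layer norm of the input (the residual identity path).
#'
#' @param state a `model_state` with `kind = "attn_mlp"`.
#' @param H a `D_M x n` matrix of token representations (columns = tokens).
#' @param layer layer index.
#' @return the transformed `D_M x n` matrix.
#' @export
attn_mlp_block <- function(state, H, layer = 1) {
  stopifnot(inherits(state, "model_state"))
  sp <- state$spec
  if (sp$kind != "attn_mlp") {
    abort("attn_mlp_block() only applies to `attn_mlp` models",
          class = "zipflearn_state_error")
  }
  M <- sp$width
  lay <- .tf_layout(sp)$layers[[layer]]
  p <- state$par
  W1 <- matrix(p[lay$W1], M, M); b1 <- p[lay$b1]
  W2 <- matrix(p[lay$W2], M, M); b2 <- p[lay$b2]
  lg <- p[lay$lg]; lb <- p[lay$lb]
  Z1 <- pmax(W1 %*% H + b1, 0)
  R <- H + W2 %*% Z1 + b2
  mu <- colMeans(R)
  va <- colMeans(R^2) - mu^2
  xhat <- sweep(sweep(R, 2, mu, "-"), 2, sqrt(va + 1e-5), "/")
  xhat * lg + lb
}

#' Save / load a model state as a portable JSON container
#'
#' The container stores the specification, the init seed and the flat
#' parameter vector as plain numbers, so checkpoints survive across
#' platforms and package versions.
#'
#' @param state a model state.
#' @param path file path (`.json`).
#' @return `write_model()` returns `state` invisibly; `read_model()` the
#'   reconstructed state.
#' @export
write_model <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  obj <- list(spec = unclass(state$spec), init_seed = state$init_seed, par = state$par)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(state)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- structure(as.list(obj$spec), class = "model_spec")
  sp$n_layers <- as.integer(sp$n_layers); sp$n_heads <- as.integer(sp$n_heads)
  sp$width <- as.integer(sp$width); sp$n_outputs <- as.integer(sp$n_outputs)
  sp$d_in <- as.integer(sp$d_in); sp$seq_len <- as.integer(sp$seq_len)
  if (!length(sp$score_scale)) sp$score_scale <- NULL
  sp$residual <- isTRUE(sp$residual); sp$embed <- isTRUE(sp$embed)
  sp$value_mode <- as.integer(sp$value_mode %||% 2L)
  structure(list(spec = sp, par = as.numeric(obj$par), init_seed = obj$init_seed),
            class = "model_state")
}
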