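# Small shared fixtures. Everything is built in code; sizes are kept tiny so
# unit tests stay fast (full-scale runs live in the acceptance helpers).

tiny_vocab <- function(K = 200, L = 10, D = 8, seed = 11) {
  build_vocabulary(K = K, L = L, D = D, seed = seed)
}

tiny_task <- function(alpha = 0, K = 200, seed = 12, layout = "pair_adjacent") {
  main_task(tiny_vocab(K = K), zipf_spec(alpha, K), layout = layout, seed = seed)
}

tiny_spec <- function(kind = "attn_only", ...) {
  model_spec(kind, n_layers = 2, d_model = 8, n_outputs = 10, d_in = 23,
             seq_len = 15, ...)
}

# a short smoke-training run on a small vocabulary
smoke_fit <- function(alpha = 0, steps = 400, K = 512, seed = 21,
                      eval_every = Inf, probe_n = 200, spec = model_spec()) {
  train_model(spec, zipf_spec(alpha, K),
              train_config(steps = steps, eval_every = eval_every,
                           probe_n = probe_n),
              seed = seed)
}

# per-coordinate finite-difference gradient check; returns median relative
# error over a random subset of coordinates
gradcheck_median <- function(spec, batch, seed = 5, n_coord = 25, eps = 1e-3) {
  st <- init_model(spec, seed = seed)
  lg <- zipflearn:::cpp_loss_grad(st$par, batch$X, as.integer(batch$y), unclass(spec))
  idx <- sample(length(st$par), n_coord)
  rel <- vapply(idx, function(i) {
    pp <- st$par; pp[i] <- pp[i] + eps
    lp <- zipflearn:::cpp_loss_grad(pp, batch$X, as.integer(batch$y), unclass(spec))$loss
    pp[i] <- st$par[i] - eps
    lm_ <- zipflearn:::cpp_loss_grad(pp, batch$X, as.integer(batch$y), unclass(spec))$loss
    num <- (lp - lm_) / (2 * eps)
    abs(num - lg$grad[i]) / max(abs(num), 1e-3)
  }, numeric(1))
  median(rel)
}
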