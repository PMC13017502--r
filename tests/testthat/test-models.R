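# Learner initialisation, forward geometry, causality and gradients.

test_that("parameter counts match the packed vector and baselines are matched", {
  for (kind in c("attn_only", "attn_mlp", "mlp", "lstm", "lstm_query_first")) {
    sp <- model_spec(kind)
    st <- init_model(sp, seed = 1)
    expect_length(st$par, n_params(sp))
  }
  ref <- n_params(model_spec("attn_only"))
  for (kind in c("mlp", "lstm", "lstm_query_first")) {
    expect_lt(abs(n_params(model_spec(kind)) - ref) / ref, 0.10)
  }
})

test_that("initialisation is deterministic under a seed", {
  expect_identical(init_model(model_spec(), 7)$par, init_model(model_spec(), 7)$par)
  expect_false(identical(init_model(model_spec(), 7)$par,
                         init_model(model_spec(), 8)$par))
})

test_that("forward pass returns L logits, normalised causal attention", {
  tk <- tiny_task()
  b <- withr::with_seed(3, zipflearn:::task_train_batch(tk, 32, 1))
  st <- init_model(model_spec(), 2)
  out <- forward(st, b$X, want_attn = TRUE)
  expect_equal(dim(out$logits), c(32, 10))
  expect_length(out$attn, 2)
  for (l in 1:2) {
    A <- out$attn[[l]]
    expect_equal(dim(A), c(15, 15, 32))
    for (i in c(1, 17, 32)) {
      expect_equal(rowSums(A[, , i]), rep(1, 15), tolerance = 1e-6)
      expect_true(all(A[, , i][upper.tri(A[, , i])] == 0))  # exact causal zeros
    }
  }
})

test_that("an untrained model responds at chance", {
  tk <- tiny_task()
  p <- withr::with_seed(5, zipflearn:::task_probe(tk, "ic_test", 1e4))
  st <- init_model(model_spec(), 3)
  acc <- mean(predict_labels(st, p$X) == p$y)
  expect_lt(abs(acc - 0.1), 0.01)
})

test_that("causality: perturbing token t leaves earlier representations unchanged", {
  tk <- tiny_task()
  b <- withr::with_seed(7, zipflearn:::task_train_batch(tk, 1, 1))
  st <- init_model(model_spec(), 4)
  h0 <- forward(st, b$X, want_hidden = TRUE)$hidden
  for (t in c(3, 9, 15)) {
    Xp <- b$X
    Xp[1:8, t] <- Xp[1:8, t] + rnorm(8)
    h1 <- forward(st, Xp, want_hidden = TRUE)$hidden
    expect_identical(h0[, seq_len(t - 1), drop = FALSE],
                     h1[, seq_len(t - 1), drop = FALSE])
    expect_false(identical(h0[, t], h1[, t]))
  }
})

test_that("forward passes are bit-stable across repeated calls", {
  tk <- tiny_task()
  b <- withr::with_seed(8, zipflearn:::task_train_batch(tk, 16, 1))
  st <- init_model(model_spec(), 5)
  expect_identical(forward(st, b$X)$logits, forward(st, b$X)$logits)
})

test_that("analytic gradients match finite differences for every kind", {
  v <- build_vocabulary(K = 50, L = 5, D = 4, seed = 3)
  tk <- main_task(v, zipf_spec(1, 50), n_context = 3, seed = 4)
  b <- withr::with_seed(5, zipflearn:::task_train_batch(tk, 16, 1))
  withr::with_seed(6, {
    for (kind in c("attn_only", "attn_mlp", "mlp", "lstm")) {
      sp <- model_spec(kind, n_layers = 2,
                       d_model = if (kind %in% c("attn_only", "attn_mlp")) 8 else NULL,
                       n_outputs = 5, d_in = 11, seq_len = 7)
      expect_lt(gradcheck_median(sp, b), 0.01)
    }
  })
})

test_that("the embedded-stream transformer variant also checks out", {
  v <- build_vocabulary(K = 50, L = 5, D = 4, seed = 3)
  tk <- main_task(v, zipf_spec(1, 50), n_context = 3, seed = 4)
  b <- withr::with_seed(5, zipflearn:::task_train_batch(tk, 16, 1))
  sp <- model_spec("attn_only", n_layers = 2, d_model = 8, n_outputs = 5,
                   d_in = 11, seq_len = 7, embed = TRUE)
  withr::with_seed(9, expect_lt(gradcheck_median(sp, b), 0.01))
  # multi-head variant
  sp2 <- model_spec("attn_only", n_layers = 2, n_heads = 2, d_model = 8,
                    n_outputs = 5, d_in = 12, seq_len = 7, embed = TRUE)
  v2 <- build_vocabulary(K = 50, L = 5, D = 5, seed = 3)
  tk2 <- main_task(v2, zipf_spec(1, 50), n_context = 3, seed = 4)
  b2 <- withr::with_seed(5, zipflearn:::task_train_batch(tk2, 16, 1))
  withr::with_seed(10, expect_lt(gradcheck_median(sp2, b2), 0.01))
})

test_that("attn_mlp block reduces to layer norm on the identity path", {
  sp <- model_spec("attn_mlp")
  st <- init_model(sp, 2)
  # zero out the first layer's feed-forward block weights
  lay <- zipflearn:::.tf_layout(sp)$layers[[1]]
  st$par[c(lay$W1, lay$b1, lay$W2, lay$b2)] <- 0
  H <- matrix(rnorm(16 * 6), 16, 6)
  out <- attn_mlp_block(st, H, layer = 1)
  ln <- apply(H, 2, function(h) (h - mean(h)) / sqrt(mean((h - mean(h))^2) + 1e-5))
  expect_equal(out, ln, tolerance = 1e-6)
  # per-token moments after layer norm
  expect_equal(colMeans(out), rep(0, 6), tolerance = 1e-5)
  expect_equal(apply(out, 2, function(x) mean(x^2)), rep(1, 6), tolerance = 1e-3)
  expect_error(attn_mlp_block(init_model(model_spec(), 1), H),
               class = "zipflearn_state_error")
})

test_that("argmax responses break ties toward the lowest label index", {
  logits <- rbind(c(0.5, 0.5, 0.1), c(-1, 2, 2))
  expect_identical(zipflearn:::.predict_labels(logits), c(1L, 2L))
})

test_that("query-first LSTM sees the query token first", {
  X <- matrix(seq_len(23 * 15), 23, 15)  # one sequence, distinguishable tokens
  Xq <- zipflearn:::.query_first_X(X, 15L)
  expect_identical(Xq[, 1], X[, 15])
  expect_identical(Xq[, 2:15], X[, 1:14])
})

test_that("model states round-trip through the JSON container", {
  st <- init_model(model_spec("lstm"), 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(st, path)
  back <- read_model(path)
  expect_equal(back$par, st$par)
  expect_identical(back$spec$kind, "lstm")
  tk <- tiny_task()
  b <- withr::with_seed(3, zipflearn:::task_probe(tk, "ic_test", 8))
  expect_identical(forward(back, b$X)$logits, forward(st, b$X)$logits)
})
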