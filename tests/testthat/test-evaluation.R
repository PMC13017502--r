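# Metric algebra, learner classification, arbitrage decomposition and the
# idealized attention templates.

test_that("double-learning index matches its closed form", {
  expect_equal(double_learning_index(1, 1, 0.1), 1)
  expect_equal(double_learning_index(0.1, 0.9, 0.1), 0)
  # plug-in arithmetic oracle: ((0.656-0.1)/0.9) * ((0.574-0.1)/0.9)
  expect_equal(double_learning_index(0.656, 0.574, 0.1),
               (0.556 / 0.9) * (0.474 / 0.9), tolerance = 1e-12)
  # algebra: symmetric in its two arguments; zero at chance for any m
  for (m in seq(0, 1, by = 0.1)) {
    expect_equal(double_learning_index(m, 0.37, 0.1),
                 double_learning_index(0.37, m, 0.1))
    expect_equal(double_learning_index(m, 0.1, 0.1), 0)
  }
  # below-chance accuracy flips the sign
  expect_lt(double_learning_index(0.05, 0.9, 0.1), 0)
  expect_error(double_learning_index(0.5, 0.5, 0), class = "zipflearn_argument_error")
  expect_error(double_learning_index(0.5, 0.5, 1), class = "zipflearn_argument_error")
})

test_that("learner classification separates the four quadrants", {
  expect_identical(classify_learner(0.98, 0.05), "in_context")
  expect_identical(classify_learner(0.05, 0.98), "in_weights")
  expect_identical(classify_learner(0.9, 0.9), "double")
  expect_identical(classify_learner(0.2, 0.3), "neither")
  expect_identical(classify_learner(c(0.9, 0.1), c(0.9, 0.1)),
                   c("double", "neither"))
  expect_error(classify_learner(0.5, 0.5, threshold = 0.05),
               class = "zipflearn_argument_error")
})

test_that("arbitrage decomposition conserves probability and flags bad trials", {
  v <- tiny_vocab()
  dist <- zipf_spec(2, v$K)
  trials <- lapply(1:60, function(s)
    make_trial("arbitrage", v, dist, trained_items = 1:30, seed = 200 + s))
  st <- init_model(model_spec(), 3)
  d <- arbitrage_decompose(st, trials, v)
  expect_gte(d$p_ic, 0); expect_gte(d$p_iw, 0)
  expect_lte(d$p_ic + d$p_iw, 1)
  # a uniform-over-labels responder lands near 1/L on both shares, and an
  # always-context / always-trained policy decomposes to (1,0) / (0,1)
  tk <- tiny_task(alpha = 2, K = 150)
  p <- withr::with_seed(3, zipflearn:::task_probe(tk, "arbitrage", 5000,
                                                  record_ranks = 1:20))
  unif <- withr::with_seed(4, sample.int(10, 5000, replace = TRUE))
  expect_lt(abs(mean(unif == p$context_label) - 0.1), 0.03)
  expect_lt(abs(mean(unif == p$trained_label) - 0.1), 0.03)
  expect_equal(mean(p$context_label == p$context_label), 1)  # always-context
  expect_equal(mean(p$trained_label == p$context_label), 0)  # never the trained one
  # forcing equal labels violates the invariant
  bad <- trials
  bad[[1]]$context_label_at_target <- bad[[1]]$trained_label
  expect_error(arbitrage_decompose(st, bad, v), class = "zipflearn_invariant_error")
})

test_that("evaluate_block scores one kind at a time", {
  v <- tiny_vocab()
  trials <- lapply(1:10, function(s) make_trial("ic_test", v, seed = s))
  st <- init_model(model_spec(), 3)
  acc <- evaluate_block(st, trials, v)
  expect_gte(acc, 0); expect_lte(acc, 1)
  mixed <- c(trials, list(make_trial("train", v, zipf_spec(0, v$K), seed = 1)))
  expect_error(evaluate_block(st, mixed, v), class = "zipflearn_argument_error")
  arb <- list(make_trial("arbitrage", v, zipf_spec(0, v$K), trained_items = 1:5, seed = 1))
  expect_error(evaluate_block(st, arb, v), class = "zipflearn_argument_error")
})

test_that("the uniform-over-context-labels policy scores 1/7", {
  expect_equal(uniform_context_policy_accuracy(analytic = TRUE), 1 / 7)
  sim <- uniform_context_policy_accuracy(n_sim = 2e4, seed = 5)
  expect_lt(abs(sim - 1 / 7), 0.01)
})

test_that("idealized templates are valid attention patterns", {
  v <- tiny_vocab()
  tr <- make_trial("ic_test", v, seed = 4)
  tpl <- idealized_templates(tr, "pair_adjacent")
  mask <- zipflearn:::.causal_mask(15)
  for (m in c(tpl$ic, tpl$iw)) {
    expect_equal(rowSums(m), rep(1, 15), tolerance = 1e-12)  # row-stochastic
    expect_true(all(m[!mask] == 0))                          # causal
  }
  # layer-1 binding: label rows one-hot on their item
  for (s in 1:7) expect_equal(tpl$ic[[1]][2 * s, 2 * s - 1], 1)
  # layer-2 induction: query row one-hot at the target label position
  expect_equal(tpl$ic[[2]][15, 2 * tr$target_position], 1)
  expect_equal(sum(tpl$ic[[2]][15, ] > 0), 1)
  # iw template: uniform over causal positions at every row
  expect_equal(tpl$iw[[1]][15, ], rep(1 / 15, 15))
  # self-similarity is exactly 1
  expect_equal(zipflearn:::.masked_cosine(tpl$ic[[1]], tpl$ic[[1]], mask), 1)
  no_target <- make_trial("iw_test", v, zipf_spec(0, v$K), trained_items = 1:5, seed = 2)
  expect_error(idealized_templates(no_target), class = "zipflearn_argument_error")
})

test_that("template similarities are bounded and well-defined for a random model", {
  fit <- smoke_fit(alpha = 0, steps = 30, K = 128, seed = 51)
  ts <- template_similarity(fit, n_trials = 20)
  expect_equal(nrow(ts), 2)              # two layers, one head
  expect_true(all(ts$sim_ic >= -1 & ts$sim_ic <= 1))
  expect_true(all(ts$sim_iw >= -1 & ts$sim_iw <= 1))
})
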