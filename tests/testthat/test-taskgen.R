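# Vocabulary, trial construction, encoding and the decode oracle.

test_that("vocabulary is deterministic, Gaussian and label-covering", {
  v1 <- build_vocabulary(K = 2^14, L = 10, D = 8, seed = 5)
  v2 <- build_vocabulary(K = 2^14, L = 10, D = 8, seed = 5)
  expect_identical(v1$items, v2$items)
  expect_identical(v1$assignment, v2$assignment)
  expect_equal(dim(v1$items), c(2^14, 8))
  expect_equal(dim(v1$labels), c(10, 8))
  # law of large numbers: coordinate variance ~ 1
  expect_equal(var(as.vector(v1$items)), 1, tolerance = 0.02)
  expect_equal(mean(as.vector(v1$items)), 0, tolerance = 0.02)
  expect_setequal(unique(v1$assignment), 1:10)
  # bijective assignment possible when K = L
  vb <- build_vocabulary(K = 10, L = 10, D = 8, seed = 6)
  expect_setequal(vb$assignment, 1:10)
  expect_error(build_vocabulary(K = 5, L = 10), class = "zipflearn_argument_error")
})

test_that("trials satisfy their per-kind invariants", {
  v <- tiny_vocab()
  dist <- zipf_spec(1, v$K)
  trained <- 1:40
  for (s in 1:20) {
    tr <- make_trial("train", v, dist, seed = s)
    expect_equal(tr$context_items[tr$target_position], tr$query_item)
    expect_equal(tr$context_labels[tr$target_position], v$assignment[tr$query_item])
    expect_equal(tr$correct_label, v$assignment[tr$query_item])

    ic <- make_trial("ic_test", v, seed = s)
    expect_true(is.na(ic$query_item))        # novel query, not in vocabulary
    expect_equal(ic$context_content[ic$target_position, ], ic$query_content)
    expect_equal(ic$correct_label, ic$context_labels[ic$target_position])

    iw <- make_trial("iw_test", v, dist, trained_items = trained, seed = s)
    expect_true(iw$query_item %in% trained)
    expect_true(all(is.na(iw$context_items)))  # context is novel
    expect_equal(iw$correct_label, v$assignment[iw$query_item])

    ar <- make_trial("arbitrage", v, dist, trained_items = trained, seed = s)
    expect_true(ar$query_item %in% trained)
    expect_equal(ar$context_items[ar$target_position], ar$query_item)
    expect_false(ar$context_label_at_target == ar$trained_label)
  }
  expect_error(make_trial("iw_test", v, dist, trained_items = integer(0)),
               class = "zipflearn_state_error")
  expect_error(make_trial("arbitrage", v, dist, trained_items = NULL),
               class = "zipflearn_state_error")
})

test_that("encoding has the documented geometry and decodes exactly", {
  v <- tiny_vocab()
  tr <- make_trial("train", v, zipf_spec(0, v$K), seed = 3)
  E <- encode_trial(tr, v, "pair_adjacent")
  expect_equal(dim(E), c(15, 23))
  # positional block is the identity
  expect_identical(E[, 9:23], diag(15))
  # pair_adjacent: item of slot s at row 2s-1, its label at row 2s
  for (s in 1:7) {
    expect_equal(E[2 * s - 1, 1:8], unname(tr$context_content[s, ]))
    expect_equal(E[2 * s, 1:8], unname(v$labels[tr$context_labels[s], ]))
  }
  expect_equal(E[15, 1:8], unname(tr$query_content))
  expect_error(encode_trial(tr, v, "bogus"), class = "zipflearn_argument_error")
})

test_that("decode oracle inverts the encoding under both layouts", {
  v <- tiny_vocab()
  for (layout in c("pair_adjacent", "ring_offset3")) {
    for (s in 1:10) {
      tr <- make_trial("train", v, zipf_spec(0.5, v$K), seed = 100 + s)
      dec <- decode_trial(encode_trial(tr, v, layout), v, layout)
      expect_identical(dec$context_items, tr$context_items)
      expect_identical(dec$context_labels, tr$context_labels)
      expect_identical(dec$query_item, tr$query_item)
      expect_identical(dec$target_position, tr$target_position)
    }
  }
})

test_that("batch encoding agrees with single-trial encoding", {
  tk <- tiny_task(alpha = 1)
  b <- withr::with_seed(9, zipflearn:::task_train_batch(tk, 5, 1))
  T_ <- tk$seq_len
  for (i in 1:5) {
    Xi <- t(b$X[, ((i - 1) * T_ + 1):(i * T_)])
    dec <- decode_trial(Xi, tk$vocab, tk$layout)
    # the batch's query item matches the decoded one and carries its label
    expect_equal(tk$vocab$assignment[dec$query_item], b$y[i])
    expect_false(is.na(dec$target_position))
  }
})

test_that("training-batch query ranks follow the configured Zipf pmf", {
  tk <- tiny_task(alpha = 2, K = 150)
  b <- withr::with_seed(13, zipflearn:::task_train_batch(tk, 1e5, 1))
  p <- zipf_pmf(seq_len(150), zipf_spec(2, 150))
  keep <- which(p * 1e5 >= 5)
  obs <- c(tabulate(b$ranks, 150)[keep], sum(!b$ranks %in% keep))
  expe <- c(p[keep], 1 - sum(p[keep])) * 1e5
  stat <- sum((obs - expe)^2 / expe)
  expect_gt(stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE), 0.001)
})

test_that("in-context and in-weights probe items never intersect the vocabulary", {
  tk <- tiny_task(alpha = 0, K = 100)
  key <- function(m) apply(round(m, 10), 1, paste, collapse = "|")
  vocab_keys <- key(tk$vocab$items)
  for (kind in c("ic_test", "iw_test")) {
    p <- withr::with_seed(31, zipflearn:::task_probe(tk, kind, 50,
                                                     record_ranks = 1:20))
    T_ <- tk$seq_len
    D <- tk$vocab$D
    for (i in 1:10) {
      Xi <- t(p$X[, ((i - 1) * T_ + 1):(i * T_)])
      items <- Xi[2 * (1:7) - 1, 1:D]
      hits <- key(items) %in% vocab_keys
      if (kind == "ic_test") {
        expect_false(any(hits))
      } else {
        expect_false(any(hits))   # context distractors all novel
        expect_true(key(Xi[15, 1:D, drop = FALSE]) %in% vocab_keys)  # query trained
      }
    }
  }
})

test_that("arbitrage probes always conflict and stay within the record", {
  tk <- tiny_task(alpha = 2, K = 150)
  p <- withr::with_seed(37, zipflearn:::task_probe(tk, "arbitrage", 500,
                                                   record_ranks = 1:10))
  expect_true(all(p$trained_label != p$context_label))
  trained_items <- tk$perm[1:10]
  # decode queries: they must be among the recorded items
  T_ <- tk$seq_len
  q <- t(p$X[1:8, (seq_len(500) - 1) * T_ + T_])
  key <- function(m) apply(round(m, 10), 1, paste, collapse = "|")
  expect_true(all(key(q) %in% key(tk$vocab$items[trained_items, , drop = FALSE])))
})

test_that("trial streams export to a tidy table", {
  v <- tiny_vocab()
  trials <- lapply(1:4, function(s) make_trial("train", v, zipf_spec(0, v$K), seed = s))
  tab <- trials_to_tibble(trials)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("kind", "query_item", "target_position", "correct_label",
                    "item1", "label7") %in% names(tab)))
})
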