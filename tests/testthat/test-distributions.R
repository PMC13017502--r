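# Zipfian pmf, sampling, deterministic block allocation and curricula.

test_that("harmonic numbers match a direct-summation oracle", {
  # independent oracle: Kahan-free reverse-order summation
  oracle <- function(n, a) sum(rev(seq_len(n))^(-a))
  expect_equal(harmonic_number(1, 3.7), 1)
  expect_equal(harmonic_number(150, 0), 150)
  expect_equal(harmonic_number(150, 2), oracle(150, 2), tolerance = 1e-12)
  expect_equal(round(harmonic_number(150, 2), 4), 1.6383)
  # monotone in n_ranks
  h <- vapply(1:50, harmonic_number, numeric(1), alpha = 1.3)
  expect_true(all(diff(h) > 0))
  expect_error(harmonic_number(0, 1), class = "zipflearn_argument_error")
})

test_that("zipf pmf normalises, decreases, and matches closed-form anchors", {
  for (a in c(0, 0.5, 1, 2, 4)) {
    spec <- zipf_spec(a, 150)
    p <- zipf_pmf(seq_len(150), spec)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    if (a > 0) expect_true(all(diff(p) < 0)) else expect_true(all(p == 1 / 150))
    # ratio property: pmf(1)/pmf(2) = 2^alpha
    expect_equal(p[1] / p[2], 2^a, tolerance = 1e-12)
  }
  expect_equal(round(zipf_pmf(1, zipf_spec(4, 150)), 4), 0.9239)
  expect_error(zipf_pmf(0, zipf_spec(1, 150)), class = "zipflearn_argument_error")
  expect_error(zipf_pmf(151, zipf_spec(1, 150)), class = "zipflearn_argument_error")
  expect_error(zipf_spec(-1, 10), class = "zipflearn_argument_error")
})

test_that("composite pmf is the stated mixture and collapses at the ends", {
  cs <- composite_spec(0.5, 2, 150)
  p <- zipflearn:::dist_pmf(cs)
  pz <- zipf_pmf(seq_len(150), zipf_spec(2, 150))
  expect_equal(p, 0.5 / 150 + 0.5 * pz, tolerance = 1e-12)
  expect_equal(zipflearn:::dist_pmf(composite_spec(1, 2, 150)),
               rep(1 / 150, 150), tolerance = 1e-12)
  expect_equal(zipflearn:::dist_pmf(composite_spec(0, 2, 150)), pz, tolerance = 1e-12)
  expect_error(composite_spec(1.2, 2, 10), class = "zipflearn_argument_error")
})

test_that("rank sampling is seeded-reproducible and matches the pmf", {
  spec <- zipf_spec(2, 150)
  r1 <- sample_ranks(spec, 1000, seed = 7)
  r2 <- sample_ranks(spec, 1000, seed = 7)
  expect_identical(r1, r2)

  draws <- sample_ranks(spec, 1e5, seed = 8)
  p <- zipf_pmf(seq_len(150), spec)
  # chi-square GOF with tail bins lumped to expected count >= 5
  keep <- which(p * 1e5 >= 5)
  obs <- c(tabulate(draws, 150)[keep], sum(!draws %in% keep))
  expe <- c(p[keep], 1 - sum(p[keep])) * 1e5
  stat <- sum((obs - expe)^2 / expe)
  expect_gt(stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE), 0.001)

  # empirical rank-1 share at alpha = 2 is ~ 1/H(150, 2) = 0.6105
  expect_equal(mean(draws == 1), 1 / harmonic_number(150, 2), tolerance = 0.01)

  # composite mixture rank-1 share ~ 0.5 * 0.6105 + 0.5 / 150
  dc <- sample_ranks(composite_spec(0.5, 2, 150), 1e5, seed = 9)
  expect_equal(mean(dc == 1), 0.5 / harmonic_number(150, 2) + 0.5 / 150,
               tolerance = 0.01)
})

test_that("deterministic block allocation reproduces the printed arrays", {
  a2 <- allocate_block_frequencies(150, 2)
  expect_identical(a2$count, c(92L, 23L, 11L, 6L, 4L, 3L, 2L, 2L, 2L,
                               1L, 1L, 1L, 1L, 1L))
  a4 <- allocate_block_frequencies(150, 4)
  expect_identical(a4$count, c(139L, 9L, 2L))
  a0 <- allocate_block_frequencies(150, 0)
  expect_identical(a0$count, rep(1L, 150))
})

test_that("allocation conserves trials and is non-increasing for any alpha", {
  for (a in c(0, 0.3, 1, 1.7, 2, 3, 4, 10)) {
    for (n in c(1, 7, 30, 150, 500)) {
      al <- allocate_block_frequencies(n, a)
      expect_identical(sum(al$count), as.integer(n))
      expect_true(all(diff(al$count) <= 0))
      expect_true(all(al$count >= 1))
    }
  }
})

test_that("the printed alpha=1 array is kept as a fixture but not generated", {
  # the alpha=1 frequencies printed for the human task follow ceiling(25/k),
  # not the c = round(n/H) rule that generates the alpha=2/alpha=4 arrays
  f <- system.file("extdata", "printed_block_allocations.csv", package = "zipflearn")
  printed <- readr::read_csv(f, show_col_types = FALSE)
  a1 <- printed[printed$alpha == 1, ]
  expect_identical(as.integer(a1$count[1:4]), c(25L, 13L, 9L, 7L))
  expect_identical(as.integer(a1$count), as.integer(ceiling(25 / a1$rank)))
  a2 <- printed[printed$alpha == 2, ]
  ours <- allocate_block_frequencies(150, 2)
  expect_identical(as.integer(a2$count), ours$count[seq_len(nrow(a2))])
})

test_that("curricula partition training and expose the right phase", {
  c1 <- curriculum_spec("C1", alpha_s = 2, n_ranks = 100, total_steps = 1000)
  expect_equal(phase_distribution(1, c1)$alpha, 0)
  expect_equal(phase_distribution(500, c1)$alpha, 0)
  expect_equal(phase_distribution(501, c1)$alpha, 2)
  c2 <- curriculum_spec("C2", alpha_s = 2, n_ranks = 100, total_steps = 1000)
  expect_equal(phase_distribution(1, c2)$alpha, 2)
  c3 <- curriculum_spec("C3", alpha_s = 2, n_ranks = 100, total_steps = 1000)
  expect_equal(vapply(c(1, 251, 501, 751), function(s) phase_distribution(s, c3)$alpha,
                      numeric(1)), c(2, 0, 2, 0))
  c4 <- curriculum_spec("C4", alpha_s = 2, n_ranks = 100, total_steps = 1000)
  expect_equal(vapply(c(1, 251, 501, 751), function(s) phase_distribution(s, c4)$alpha,
                      numeric(1)), c(0, 2, 0, 2))
  # every step maps to exactly one phase
  for (cur in list(c1, c2, c3, c4)) {
    alphas <- vapply(seq_len(1000), function(s) phase_distribution(s, cur)$alpha,
                     numeric(1))
    expect_length(alphas, 1000)
  }
  expect_error(phase_distribution(1001, c1), class = "zipflearn_argument_error")
  expect_error(
    curriculum_spec("custom", n_ranks = 10, total_steps = 100,
                    phases = tibble::tibble(from = c(1, 40), to = c(50, 100),
                                            alpha = c(0, 2))),
    class = "zipflearn_argument_error"
  )
})

test_that("distribution specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  for (spec in list(zipf_spec(2, 150), composite_spec(0.3, 4, 99),
                    curriculum_spec("C2", 2, 64, 800))) {
    write_dist_spec(spec, path)
    back <- read_dist_spec(path)
    expect_equal(zipflearn:::dist_pmf(if (inherits(spec, "curriculum_spec"))
      phase_distribution(1, spec) else spec),
      zipflearn:::dist_pmf(if (inherits(back, "curriculum_spec"))
        phase_distribution(1, back) else back))
    expect_s3_class(back, class(spec)[1])
  }
})
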