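# Training-data distributions: Zipfian (rank-frequency), composite
# (uniform/skewed mixture) and curricula (phase schedules over a training
# run), plus the deterministic per-rank trial allocation used for
# human-style 150-trial blocks.

#' Zipfian (rank-frequency) distribution specification
#'
#' A Zipfian distribution over `n_ranks` ranked elements assigns rank `k`
#' (counting from 1) the probability `k^(-alpha) / H(n_ranks, alpha)`, where
#' `H` is the generalised harmonic number. `alpha = 0` is the uniform
#' distribution (maximal diversity); large `alpha` concentrates nearly all
#' mass on the first rank (maximal redundancy).
#'
#' @param alpha skewness exponent, `>= 0`.
#' @param n_ranks support size, `>= 1`.
#' @return an object of class `c("zipf_spec", "dist_spec")`.
#' @export
#' @examples
#' zipf_spec(2, 150)
zipf_spec <- function(alpha, n_ranks) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.numeric(n_ranks), length(n_ranks) == 1)
  if (alpha < 0) abort("`alpha` must be >= 0", class = "zipflearn_argument_error")
  if (n_ranks < 1) abort("`n_ranks` must be >= 1", class = "zipflearn_argument_error")
  structure(
    list(alpha = as.double(alpha), n_ranks = as.integer(n_ranks)),
    class = c("zipf_spec", "dist_spec")
  )
}

#' Composite (uniform + skewed mixture) distribution specification
#'
#' With probability `p_uniform` a draw comes from the uniform distribution
#' over the support and otherwise from a skewed Zipfian with exponent
#' `alpha_skewed`. `p_uniform = 1` recovers `zipf_spec(0, n_ranks)` and
#' `p_uniform = 0` recovers `zipf_spec(alpha_skewed, n_ranks)`.
#'
#' @param p_uniform mixing fraction in `[0, 1]`.
#' @param alpha_skewed exponent of the skewed component, `> 0`.
#' @param n_ranks support size shared by both components.
#' @return an object of class `c("composite_spec", "dist_spec")`.
#' @export
composite_spec <- function(p_uniform, alpha_skewed, n_ranks) {
  stopifnot(is.numeric(p_uniform), length(p_uniform) == 1)
  if (p_uniform < 0 || p_uniform > 1) {
    abort("`p_uniform` must be in [0, 1]", class = "zipflearn_argument_error")
  }
  if (alpha_skewed <= 0) abort("`alpha_skewed` must be > 0", class = "zipflearn_argument_error")
  if (n_ranks < 1) abort("`n_ranks` must be >= 1", class = "zipflearn_argument_error")
  structure(
    list(p_uniform = as.double(p_uniform), alpha_skewed = as.double(alpha_skewed),
         n_ranks = as.integer(n_ranks)),
    class = c("composite_spec", "dist_spec")
  )
}

#' @export
print.zipf_spec <- function(x, ...) {
  cat(sprintf("<zipf_spec> alpha = %g, n_ranks = %d\n", x$alpha, x$n_ranks))
  invisible(x)
}

#' @export
print.composite_spec <- function(x, ...) {
  cat(sprintf("<composite_spec> p_uniform = %g, alpha_skewed = %g, n_ranks = %d\n",
              x$p_uniform, x$alpha_skewed, x$n_ranks))
  invisible(x)
}

#' Generalised harmonic number
#'
#' Computes `H(n, alpha) = sum_{k=1}^{n} k^(-alpha)`, the normalisation
#' constant of the Zipfian rank-frequency distribution.
#'
#' @param n_ranks number of terms, `>= 1`.
#' @param alpha exponent, `>= 0`.
#' @return the harmonic number (a positive scalar).
#' @export
#' @examples
#' harmonic_number(150, 2)
harmonic_number <- function(n_ranks, alpha) {
  stopifnot(is.numeric(n_ranks), length(n_ranks) == 1, is.numeric(alpha))
  if (n_ranks < 1) abort("`n_ranks` must be >= 1", class = "zipflearn_argument_error")
  if (alpha < 0) abort("`alpha` must be >= 0", class = "zipflearn_argument_error")
  sum(seq_len(n_ranks)^(-alpha))
}

#' Zipfian probability mass at given ranks
#'
#' @param rank integer rank(s), 1-based, within the support of `spec`.
#' @param spec a [zipf_spec()].
#' @return numeric vector of probabilities.
#' @export
#' @examples
#' zipf_pmf(1, zipf_spec(4, 150))
zipf_pmf <- function(rank, spec) {
  stopifnot(inherits(spec, "zipf_spec"))
  if (any(rank < 1 | rank > spec$n_ranks) || any(rank != floor(rank))) {
    abort("`rank` must be an integer in [1, n_ranks]", class = "zipflearn_argument_error")
  }
  rank^(-spec$alpha) / harmonic_number(spec$n_ranks, spec$alpha)
}

# full pmf vector over the support of any distribution spec
dist_pmf <- function(spec) {
  UseMethod("dist_pmf")
}

#' @export
dist_pmf.zipf_spec <- function(spec) {
  k <- seq_len(spec$n_ranks)
  w <- k^(-spec$alpha)
  w / sum(w)
}

#' @export
dist_pmf.composite_spec <- function(spec) {
  k <- seq_len(spec$n_ranks)
  w <- k^(-spec$alpha_skewed)
  spec$p_uniform / spec$n_ranks + (1 - spec$p_uniform) * w / sum(w)
}

#' Sample item ranks from a distribution specification
#'
#' Draws i.i.d. ranks from a Zipfian or composite distribution. With the
#' same `seed` the sequence is identical across calls; with `seed = NULL`
#' the current RNG stream is consumed.
#'
#' @param spec a [zipf_spec()] or [composite_spec()].
#' @param n_draws number of draws, `>= 1`.
#' @param seed optional integer seed.
#' @return an integer vector of ranks in `[1, n_ranks]`.
#' @export
sample_ranks <- function(spec, n_draws, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (n_draws < 1) abort("`n_draws` must be >= 1", class = "zipflearn_argument_error")
  draw <- function() {
    pmf <- dist_pmf(spec)
    # inverse-cdf sampling keeps the cost at O(n_ranks + n log n_ranks)
    cum <- cumsum(pmf)
    cum[length(cum)] <- 1
    findInterval(runif(n_draws), cum, left.open = TRUE) + 1L
  }
  if (is.null(seed)) draw() else with_stream(seed, draw())
}

#' Deterministic per-rank trial counts for a human-style training block
#'
#' Converts a Zipfian exponent into the deterministic frequency allocation
#' used for fixed-length training blocks: with
#' `c = round(n_trials / H(n_trials, alpha))`, rank `k` receives
#' `ceiling(c / k^alpha)` trials, accumulated in rank order for as long as
#' the running total stays within `n_trials`; any remaining trials are
#' filled with novel singleton items (one trial each). Counts always sum to
#' exactly `n_trials` and are non-increasing. At `alpha = 0` every item is
#' novel and appears once.
#'
#' @param n_trials block length, `>= 1`.
#' @param alpha Zipfian exponent, `>= 0`.
#' @return a tibble with columns `rank` and `count`.
#' @export
#' @examples
#' allocate_block_frequencies(150, 2)
allocate_block_frequencies <- function(n_trials, alpha) {
  stopifnot(is.numeric(n_trials), length(n_trials) == 1)
  if (n_trials < 1) abort("`n_trials` must be >= 1", class = "zipflearn_argument_error")
  if (alpha < 0) abort("`alpha` must be >= 0", class = "zipflearn_argument_error")
  n_trials <- as.integer(n_trials)
  c0 <- round(n_trials / harmonic_number(n_trials, alpha))
  counts <- integer(0)
  total <- 0L
  k <- 1
  repeat {
    cnt <- as.integer(ceiling(c0 / k^alpha))
    if (cnt < 1L || total + cnt > n_trials) break
    counts <- c(counts, cnt)
    total <- total + cnt
    if (total == n_trials) break
    k <- k + 1
  }
  if (total < n_trials) {
    counts <- c(counts, rep(1L, n_trials - total))
  }
  tibble(rank = seq_along(counts), count = counts)
}

#' Curriculum specification: an ordered schedule of Zipfian phases
#'
#' A curriculum partitions a training run into phases, each sampling from
#' its own Zipfian distribution. The named curricula operate on the two
#' components of a composite distribution (uniform `alpha = 0` and skewed
#' `alpha_s`):
#' \describe{
#'   \item{C1}{uniform first half, skewed second half (diversity first).}
#'   \item{C2}{skewed first half, uniform second half.}
#'   \item{C3}{quarters: skewed, uniform, skewed, uniform (interleaved).}
#'   \item{C4}{quarters: uniform, skewed, uniform, skewed.}
#' }
#' Custom curricula supply `phases` directly as a data frame with columns
#' `from`, `to`, `alpha` whose spans must partition `1:total_steps`.
#'
#' @param name one of `"C1"`, `"C2"`, `"C3"`, `"C4"` or `"custom"`.
#' @param alpha_s exponent of the skewed phases, `> 0`.
#' @param n_ranks support size of every phase.
#' @param total_steps length of the training run the spans refer to.
#' @param phases optional tibble of custom phases (`from`, `to`, `alpha`).
#' @return an object of class `c("curriculum_spec", "dist_spec")`.
#' @export
#' @examples
#' curriculum_spec("C1", alpha_s = 2, n_ranks = 2^14, total_steps = 5000)
curriculum_spec <- function(name = c("C1", "C2", "C3", "C4", "custom"),
                            alpha_s = 2, n_ranks, total_steps, phases = NULL) {
  name <- match.arg(name)
  if (name != "custom") {
    if (alpha_s <= 0) abort("`alpha_s` must be > 0", class = "zipflearn_argument_error")
    half <- floor(total_steps / 2)
    q <- floor(total_steps / 4)
    cuts <- switch(name,
      C1 = tibble(from = c(1, half + 1), to = c(half, total_steps), alpha = c(0, alpha_s)),
      C2 = tibble(from = c(1, half + 1), to = c(half, total_steps), alpha = c(alpha_s, 0)),
      C3 = tibble(from = c(1, q + 1, 2 * q + 1, 3 * q + 1),
                  to = c(q, 2 * q, 3 * q, total_steps),
                  alpha = c(alpha_s, 0, alpha_s, 0)),
      C4 = tibble(from = c(1, q + 1, 2 * q + 1, 3 * q + 1),
                  to = c(q, 2 * q, 3 * q, total_steps),
                  alpha = c(0, alpha_s, 0, alpha_s))
    )
    phases <- cuts
  } else {
    phases <- as_tibble(phases)
    stopifnot(all(c("from", "to", "alpha") %in% names(phases)))
  }
  # spans must partition the run: no gaps, no overlaps
  covered <- unlist(purrr::map2(phases$from, phases$to, seq))
  if (!identical(sort(covered), seq_len(total_steps))) {
    abort("curriculum phases must partition 1:total_steps with no gaps or overlaps",
          class = "zipflearn_argument_error")
  }
  structure(
    list(name = name, phases = phases, n_ranks = as.integer(n_ranks),
         total_steps = as.integer(total_steps), alpha_s = alpha_s),
    class = c("curriculum_spec", "dist_spec")
  )
}

#' @export
print.curriculum_spec <- function(x, ...) {
  cat(sprintf("<curriculum_spec> %s over %d steps (n_ranks = %d)\n",
              x$name, x$total_steps, x$n_ranks))
  print(x$phases)
  invisible(x)
}

#' Distribution in force at a given training step
#'
#' @param step_or_block training-step (or block) index.
#' @param curriculum a [curriculum_spec()].
#' @return the [zipf_spec()] whose span covers the index.
#' @export
phase_distribution <- function(step_or_block, curriculum) {
  stopifnot(inherits(curriculum, "curriculum_spec"))
  i <- which(curriculum$phases$from <= step_or_block & curriculum$phases$to >= step_or_block)
  if (length(i) != 1) {
    abort("index outside every curriculum phase", class = "zipflearn_argument_error")
  }
  zipf_spec(curriculum$phases$alpha[i], curriculum$n_ranks)
}

#' Serialise / deserialise a distribution spec
#'
#' Distribution specifications round-trip through YAML so that a run is
#' reproducible from its config file alone.
#'
#' @param spec a distribution spec.
#' @param path file path.
#' @return `write_dist_spec()` returns `spec` invisibly; `read_dist_spec()`
#'   returns the reconstructed spec.
#' @export
write_dist_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dist_spec"))
  fields <- unclass(spec)
  fields$phases <- if (!is.null(fields$phases)) as.list(as.data.frame(fields$phases))
  yaml::write_yaml(c(list(class = class(spec)[1]), fields[!vapply(fields, is.null, TRUE)]), path)
  invisible(spec)
}

#' @rdname write_dist_spec
#' @export
read_dist_spec <- function(path) {
  d <- yaml::read_yaml(path)
  switch(d$class,
    zipf_spec = zipf_spec(d$alpha, d$n_ranks),
    composite_spec = composite_spec(d$p_uniform, d$alpha_skewed, d$n_ranks),
    curriculum_spec = {
      if (d$name == "custom") {
        curriculum_spec("custom", n_ranks = d$n_ranks, total_steps = d$total_steps,
                        phases = as_tibble(d$phases))
      } else {
        curriculum_spec(d$name, alpha_s = d$alpha_s, n_ranks = d$n_ranks,
                        total_steps = d$total_steps)
      }
    },
    abort(sprintf("unknown spec class in file: %s", d$class))
  )
}

#' @export
tidy.zipf_spec <- function(x, ...) {
  tibble(rank = seq_len(x$n_ranks), probability = dist_pmf(x))
}

#' @export
tidy.composite_spec <- function(x, ...) {
  tibble(rank = seq_len(x$n_ranks), probability = dist_pmf(x))
}
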