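# Seed-stream derivation: one master seed splits into named independent
# streams (vocabulary, model init, trial stream, probes, ...) so components
# can be varied independently while staying reproducible.

# deterministic 31-bit hash of a string
.stream_hash <- function(stream) {
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  h
}

#' Derive a child seed from a master seed and a stream name
#'
#' Splitting one master seed into named streams keeps the vocabulary, the
#' model initialisation and the trial stream independently reproducible: the
#' same master seed always yields the same child seeds, and two distinct
#' stream names (or replicate indices) yield unrelated ones.
#'
#' @param master integer master seed.
#' @param stream character stream name (e.g. `"vocab"`, `"init"`, `"trials"`).
#' @param index optional replicate index folded into the seed.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "vocab")
#' derive_seed(1, "vocab", index = 2)
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stream))
  h <- .stream_hash(stream)
  s <- (abs(as.double(master)) %% 2147483647) * 48271 %% 2147483647
  out <- (s + h * 69621 + as.double(index) * 16807) %% 2147483646
  as.integer(out + 1)
}

# run code under a temporary seed without disturbing the caller's RNG
with_stream <- function(seed, code) {
  withr::with_seed(seed, code)
}
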