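#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in connfit flows from a single master seed through named
#' substreams, so that any stage (timeseries, planted weights, permutations
#' for one model, ...) can be regenerated independently of execution order.
#' The derivation hashes the key components with a 31-ary polynomial hash
#' modulo 2^31 - 1 and folds in the master seed; it is deterministic across
#' platforms and sessions.
#'
#' @param master_seed integer master seed.
#' @param ... key components (coerced to character) naming the substream,
#'   e.g. `derive_seed(1, "perm", "L01", "domain_03")`.
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "timeseries", 1, 2)
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed))
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + abs(master_seed)) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_substream <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
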