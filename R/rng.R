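# Named substreams derived from a single master seed.
#
# Each consumer of randomness (tuning draw, gains, per-trace noise, disk
# placement ...) seeds R's RNG with a hash of (master seed, stream name,
# index).  Extending the odor panel therefore never perturbs the gain draws,
# and any trace can be regenerated in isolation.

#' Derive a deterministic substream seed from a master seed
#'
#' @param master integer master seed (one per neuron by convention).
#' @param name character stream name, e.g. `"tuning"`, `"gains"`, `"noise"`.
#' @param index optional non-negative integer distinguishing draws within a
#'   stream (e.g. one per trace).
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1L, "tuning")
#' @export
substream_seed <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(name), length(name) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(master %% m)
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.double(index) %% m)) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}
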