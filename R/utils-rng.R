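#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Simulations use independent named random streams (data, model init, batch
#' order, timing, selection) so that changing one component never perturbs the
#' randomness consumed by another. Sub-seeds are derived from the master seed
#' and a sequence of string/integer labels with a small polynomial hash; the
#' result always fits in a 32-bit signed integer.
#'
#' @param seed Integer master seed.
#' @param ... Labels (character or integer) identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(labels)
  m <- 2147483647 # 2^31 - 1
  h <- (abs(as.numeric(seed)) %% m)
  for (cc in codes) {
    h <- (h * 31 + cc) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_stream <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
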