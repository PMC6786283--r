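#' Noise specification for the synthetic generators
#'
#' Homoscedastic Gaussian noise in the signal's own units, plus the seed that
#' makes a generator call reproducible. Identical `(parameters, seed)` pairs
#' produce bit-identical output.
#'
#' @param sd standard deviation, in the units of the signal the generator
#'   emits (fluorescence a.u., ucal, normalized intensity, ...); must be >= 0
#' @param seed integer seed
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(sd = 0, seed = 1L) {
  stopifnot(is.numeric(sd), length(sd) == 1, sd >= 0, is.finite(sd))
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  structure(list(sd = sd, seed = seed), class = "noise_spec")
}

#' Derive a child seed from a global seed and a counter
#'
#' One global seed expands to per-generator child seeds by a fixed counter
#' scheme, so adding a later generator call never perturbs earlier streams.
#' The map is one step of a 32-bit linear congruential generator offset by the
#' counter: `(1103515245 * seed + 12345 + counter) mod 2^31`.
#'
#' @param seed global integer seed
#' @param counter non-negative integer index of the stream
#' @return integer child seed in `[0, 2^31)`
#' @export
child_seed <- function(seed, counter) {
  stopifnot(counter >= 0)
  # 64-bit double arithmetic is exact here: products stay below 2^53
  s <- (as.numeric(seed) %% 2^31)
  as.integer(((1103515245 * s) %% 2^31 + 12345 + as.numeric(counter)) %% 2^31)
}

# run expr with a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
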