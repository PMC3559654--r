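#' Derive a named random stream seed from a base seed
#'
#' All randomness in the phantom generators flows from a single base seed via
#' named streams, so that adding one source of randomness (say a new tissue)
#' never perturbs the draws of another. The stream seed is a deterministic
#' 31-bit hash of the base seed and the stream name.
#'
#' @param seed integer base seed.
#' @param stream character stream name, e.g. `"noise"`, `"speckle"`.
#' @return an integer seed below 2^31.
#' @keywords internal
stream_seed <- function(seed, stream) {
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a named stream seed, restoring the caller's RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# round() half-away-from-zero, matching how printed tables are rounded.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
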