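#' Derive a child seed from a master seed and a stream name
#'
#' All randomness in the package flows from one master seed. Independent
#' random streams (per autoencoder layer, scatter matrix, final feature map,
#' data splits, ...) get their own child seed derived deterministically from
#' the master seed and a short stream label, so adding a stream never shifts
#' the draws of another.
#'
#' The rule is a small polynomial hash of the label folded into the master
#' seed modulo 2^31 - 1 (a valid R seed range); it is documented so that the
#' same (seed, stream) pair always maps to the same child seed across
#' platforms and sessions.
#'
#' @param master_seed integer master seed.
#' @param stream character scalar naming the stream, e.g. `"ae1"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  stopifnot(is.character(stream), length(stream) == 1L, nzchar(stream))
  m <- 2147483647 # 2^31 - 1, prime
  s <- abs(as.numeric(master_seed)) %% m
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% m
  # keep intermediate products < 2^53 so double arithmetic stays exact
  as.integer((s * 48271 %% m + h * 69621 %% m) %% (m - 1) + 1)
}

# run expr with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
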