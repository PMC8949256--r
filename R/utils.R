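# Internal helpers: seeded evaluation and deterministic sub-seed derivation.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Splitmix-style integer mixing: the master seed and stream index are
#' combined by multiply-xor-shift rounds carried out in 32-bit arithmetic.
#' Used everywhere a compound stochastic process (a noise chain, a training
#' run) needs independent, order-insensitive per-stage streams: stage `i` of
#' a chain always receives `derive_seed(master_seed, i)` no matter when it
#' is evaluated.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer stream index.
#' @return A single non-negative integer seed, strictly below 2^31.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(length(master_seed) == 1L, length(index) == 1L, is.finite(master_seed), is.finite(index))
  # 32-bit mixing on the bit patterns; bitwAnd keeps everything in range
  x <- bitwXor(as.integer(master_seed %% 2147483647),
               as.integer((index * 1640531527) %% 2147483647))
  for (k in c(374761393L, 668265263L)) {
    x <- bitwXor(x, bitwShiftR(x, 15L))
    x <- as.integer((as.double(x %% 2147483647L) * k) %% 2147483647)
    x <- bitwXor(x, bitwShiftR(x, 13L))
  }
  abs(x) %% 2147483647L
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_param <- function(...) stop(..., call. = FALSE)
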