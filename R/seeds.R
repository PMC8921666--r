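#' Derive a child seed from a master seed
#'
#' Every source of randomness in a benchmark run (fold assignment, control
#' draws, the synthetic generator's stages) draws its own child seed from the
#' single master seed through this function, so any stage can be reproduced in
#' isolation without replaying the whole run.
#'
#' The scheme is a multiplicative mixing hash over the master seed, the bytes
#' of the purpose label and the index, reduced modulo 2^31 - 1 (a Mersenne
#' prime), so results are exact in double precision and valid `set.seed()`
#' inputs on any platform.
#'
#' @param master integer master seed.
#' @param purpose character label for the consumer (e.g. "folds", "draw").
#' @param index optional integer distinguishing repeated consumers (e.g. the
#'   control-draw number). Default 0.
#' @return an integer in \[1, 2^31 - 2\].
#' @export
#' @examples
#' child_seed(42, "folds")
#' child_seed(42, "draw", 17)
child_seed <- function(master, purpose, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(purpose))
  m <- 2147483647 # 2^31 - 1
  x <- (abs(master) %% m)
  x <- (x * 69069 + 12345) %% m
  for (v in utf8ToInt(purpose)) x <- (x * 69069 + v) %% m
  x <- (x * 69069 + (abs(index) %% m)) %% m
  as.integer(x %% (m - 2) + 1)
}

# Hash an arbitrary R object to a hex string (used to stamp output tables so
# two runs with identical configuration are recognisably identical).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  m <- 2147483647
  h1 <- 0; h2 <- 5381
  for (v in utf8ToInt(s)) {
    h1 <- (h1 * 69069 + v) %% m
    h2 <- (h2 * 33 + v) %% m
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}
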