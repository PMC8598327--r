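# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Every source of randomness in the package (fold assignment, forest seeds,
#' generator draws, learner seeds) is seeded from a single master seed through
#' this derivation, so that one integer reproduces an entire run. The result
#' always fits in a 32-bit signed integer.
#'
#' @param master Master seed (single integer).
#' @param salt Integer salt distinguishing the consumer (layer index, forest
#'   index, ...).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, salt = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  # Affine map modulo the Mersenne prime 2^31 - 1; cheap, deterministic and
  # well-spread for small consecutive salts.
  m <- 2147483647
  as.integer((abs(master) %% m * 7919 + abs(salt) %% m * 104729 + 17) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dsn <- function(...) stop(sprintf(...), call. = FALSE)

warn_dsn <- function(...) warning(sprintf(...), call. = FALSE)

# Population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# Row-normalize a non-negative matrix; all-zero rows become uniform.
normalize_rows <- function(p) {
  s <- rowSums(p)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    p[zero, ] <- 1
    s[zero] <- ncol(p)
  }
  p / s
}

# argmax with lowest-index tie-break (max.col breaks ties at random).
argmax_first <- function(p) {
  max.col(p, ties.method = "first")
}
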