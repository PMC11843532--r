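#' Derive a sub-seed from a run-level seed
#'
#' Every stochastic operation in synflim takes an explicit integer seed. A
#' run-level seed is fanned out to per-stage / per-timepoint sub-seeds by a
#' fixed counter scheme so that a single seed reproduces an entire pipeline
#' run while stages stay statistically decoupled.
#'
#' The scheme is `(seed + 1000003 * index) mod (2^31 - 1)`, with `index`
#' starting at 0 for the first consumer.
#'
#' @param seed Integer run-level seed.
#' @param index Non-negative integer counter (which consumer this is).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
subseed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% (2^31 - 1))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Stable 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to
# stamp pipeline outputs with a configuration fingerprint.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
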