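# Internal helpers shared across modules.

#' Derive a deterministic sub-seed for a named random stream
#'
#' All randomness in the package flows from a single user seed; each pipeline
#' stage draws from its own named substream so that changing one stage's
#' draws cannot silently reorder another's.
#'
#' @param seed integer master seed.
#' @param stream character stream name (e.g. "panel", "cohort:GBM1").
#' @return an integer seed in [0, 2^31 - 1).
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(codes)) {
    h <- (h * 31 + codes[k] * k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a named substream without touching the caller's RNG.
with_stream <- function(seed, stream, expr) {
  withr::with_seed(derive_seed(seed, stream), expr)
}

# all subsets of `x` of size 0..k, as a list (size-0 subset = character(0)/integer(0))
subsets_up_to <- function(x, k) {
  out <- list(x[0])
  k <- min(k, length(x))
  if (k >= 1) {
    for (m in seq_len(k)) {
      cm <- utils::combn(x, m, simplify = FALSE)
      out <- c(out, cm)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
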