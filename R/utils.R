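# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package do
#' not disturb the caller's random stream.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation from one global seed. Mixes stream
# labels and indices with distinct primes, folded into [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed) %% 2147483629
  primes <- c(7919, 104729, 1299709, 15485863, 32452843)
  for (i in seq_along(parts)) {
    p <- primes[((i - 1L) %% length(primes)) + 1L]
    v <- if (is.character(parts[[i]])) {
      sum(utf8ToInt(parts[[i]]) * seq_along(utf8ToInt(parts[[i]])))
    } else {
      as.double(parts[[i]])
    }
    h <- (h * 31 + v * p) %% 2147483629
  }
  as.integer(h)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
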