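# Internal helpers: seeded evaluation and substream derivation.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. NULL seed runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible substream seed
#'
#' Deterministically maps a global seed plus a named substream and counter to
#' a 31-bit integer seed. Used throughout so that every stochastic step of a
#' larger run (phantom draws, noise realizations, scheme generation) receives
#' its own documented seed derived from one global seed.
#'
#' @param seed Integer global seed.
#' @param stream Character scalar naming the substream (e.g. `"phantom"`).
#' @param counter Non-negative integer distinguishing repeats in a stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "phantom", 3)
#' @export
derive_seed <- function(seed, stream = "main", counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  x <- (as.double(seed) %% 2147483647) * 48271 + h * 69621 + as.double(counter) * 16807
  as.integer(x %% 2147483629 + 1)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}
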