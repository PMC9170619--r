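# Private, replayable random streams.
#
# Agents and the session runner each own an independent stream so that a
# decision replayed with the same seed and view is identical no matter what
# other randomness ran in between. A stream is an environment holding a saved
# .Random.seed; stream_eval() swaps it into place, evaluates, and saves the
# advanced state back, leaving the caller's RNG untouched.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Mix a 31-bit seed with one or more integer keys. All arithmetic stays below
# 2^48, exact in doubles. Results are in [0, 2147483646], valid for set.seed().
mix_seed <- function(seed, key) {
  x <- abs(as.numeric(seed)) %% 2147483647
  for (k in as.numeric(key)) {
    x <- (x * 69069 + (abs(k) %% 2147483647) + 1) %% 2147483647
  }
  x
}

#' Derive a child seed from a master seed
#'
#' Deterministically mixes a master seed with a sequence of integer keys
#' (e.g. triad id, position) so that independent components of a simulation
#' get distinct, reproducible seeds without sharing a stream.
#'
#' @param seed master seed (integer-valued).
#' @param ... integer keys identifying the child (triad index, position, ...).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  as.integer(mix_seed(seed, c(...)))
}

#' Create a private random stream
#'
#' @param seed integer seed for the stream.
#' @return an environment of class `coalsim_stream` holding the stream state.
#' @seealso [stream_eval()]
#' @export
make_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "coalsim_stream"
  e
}

#' Evaluate an expression using a private stream
#'
#' Swaps the stream's saved state into `.Random.seed`, evaluates `expr`,
#' stores the advanced state back into the stream, and restores the caller's
#' RNG state.
#'
#' @param stream a stream from [make_stream()].
#' @param expr expression to evaluate (typically a call to `sample`, `runif`,
#'   ...).
#' @return the value of `expr`.
#' @export
stream_eval <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
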