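# internal helpers: logging and reproducible per-set RNG substreams

.log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Derive a deterministic RNG substream seed
#'
#' Results must not depend on the order in which treatment sets are evaluated,
#' so each set gets its own seed derived from the master seed and the set's
#' index in the (deterministically sorted) set list. A run is then fully
#' reproducible whether sets are scored serially or concurrently.
#'
#' @param seed master integer seed of the run.
#' @param index 1-based index of the substream (e.g. the set's position).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # multiplicative congruential step (Lehmer/MINSTD modulus), done in double
  # precision: all intermediates stay below 2^53 so the arithmetic is exact
  m <- 2147483647
  s <- (abs(seed) %% m)
  s <- (s * 48271 + index * 1009 + 1) %% m
  as.integer(s)
}

#' Evaluate an expression under a local RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state, so
#' randomized steps (e.g. [estimate_null()], [random_signature()]) can be made
#' reproducible without disturbing the surrounding session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
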