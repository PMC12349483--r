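# RNG helpers.  Training draws from several logically distinct sources of
# randomness (initialization, shuffling, dropout, penalty subsampling); the
# subsampling stream is kept separate so that changing e.g. the dropout rate
# does not silently shift which bases the penalties see.

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# a resumable RNG stream: an environment carrying its own .Random.seed
new_rng_stream <- function(seed) {
  state <- with_preserved_rng(seed, get(".Random.seed", globalenv()))
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
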