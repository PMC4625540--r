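## Seed handling.
##
## All randomized operations take an integer seed and draw from a private
## RNG stream, leaving the caller's .Random.seed untouched.  Sub-seeds are
## derived from one master seed by a fixed multiplicative scheme (Lehmer
## step modulo the Mersenne prime 2^31 - 1), so a single integer
## reproducibly fixes every source of randomness.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k) %% 2147483647)
}

make_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    if (is.null(state)) {
      set.seed(as.integer(seed) %% 2147483647L)
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    f()
  }
  list(
    # sample `size` elements of x without replacement (safe for length-1 x)
    sample = function(x, size = length(x)) run(function() x[sample.int(length(x), size)]),
    runif = function(n = 1L) run(function() stats::runif(n)),
    # `n` uniform integers in 1..max
    int = function(n, max) run(function() sample.int(max, n, replace = TRUE)),
    shuffle = function(x) run(function() x[sample.int(length(x), length(x))])
  )
}
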