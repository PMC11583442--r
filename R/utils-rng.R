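# Seeded RNG helpers. Every stochastic stage draws from a seed derived from
# the run seed, so a whole run is reproducible bit-for-bit while stages stay
# independent of one another's draw counts.

#' Derive a stage seed from a run seed
#'
#' Deterministic mixing of a run seed and an integer salt into a 31-bit seed,
#' so distinct pipeline stages get distinct but reproducible streams.
#'
#' @param seed Run seed (integer).
#' @param salt Stage-specific integer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) * 7919 + abs(as.numeric(salt)) * 104729) %% 2147483646)
}

#' Evaluate an expression under a temporary seed
#'
#' Sets the RNG seed, evaluates `expr`, then restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(as.integer(seed))
  expr
}

# A persistent, isolated RNG stream: each call advances the stream without
# touching (or being touched by) the caller's global RNG state.
local_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  with_seed(as.integer(seed), {
    state$s <- get(".Random.seed", globalenv(), inherits = FALSE)
  })
  run <- function(fn) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    assign(".Random.seed", state$s, envir = globalenv())
    on.exit({
      state$s <- get(".Random.seed", globalenv(), inherits = FALSE)
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      }
    })
    fn()
  }
  list(
    sample = function(x, size = length(x), replace = FALSE, prob = NULL) {
      run(function() x[sample.int(length(x), size, replace = replace, prob = prob)])
    },
    sample_int = function(n, size = n, replace = FALSE) {
      run(function() sample.int(n, size, replace = replace))
    },
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    draw_seed = function() run(function() sample.int(2147483646L, 1L))
  )
}
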