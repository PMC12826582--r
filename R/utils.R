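# internal helpers shared across modules

# Two-sided conditional Fisher p for a 2x2 table with cells
#   affected:   y1 (treated), y0 (control)
#   unaffected: n1 - y1,      n0 - y0
# Convention: sum of hypergeometric probabilities <= P(observed) (with a
# small relative tolerance, as in stats::fisher.test).
fisher_p_two_sided <- function(y1, n1, y0, n0) {
  m <- y1 + y0              # total affected
  lo <- max(0L, m - n0)
  hi <- min(n1, m)
  if (n1 == 0L || n0 == 0L) return(1)
  support <- lo:hi
  probs <- dhyper(support, n1, n0, m)
  p_obs <- probs[support == y1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# deterministic derived seed below 2^31, for per-tag RNG streams
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# run expr under a local RNG state seeded from (seed, tag); restores state
with_stream <- function(seed, tag, expr) {
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
  set.seed(derive_seed(seed, tag))
  force(expr)
}

`%||%` <- rlang::`%||%`
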