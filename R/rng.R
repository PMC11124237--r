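#' Derive a named substream seed from a master seed
#'
#' All stochastic stages of a simulation draw from independent named
#' substreams derived from one master seed, so that e.g. the operating-beam
#' realization is bit-identical whether or not a probe beam is added.
#' The derivation is a polynomial string hash folded into the master seed,
#' kept below 2^31.
#'
#' @param seed master seed (single integer).
#' @param name substream name, e.g. `"op.arrivals"`.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, name) {
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so simulation substreams do not
#' disturb the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
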