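#' @importFrom stats plogis qlogis rbinom rnorm runif uniroot quantile setNames
#' @importFrom utils head
#' @importFrom rlang .data
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds from one master seed, all below 2^31,
# so each sampling stage can be regenerated independently.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# floor(x + 0.5): round-half-up, used for census projections.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
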