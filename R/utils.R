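# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, seeds it, evaluates `code`, and restores the
#' previous state, so seeded operations never perturb the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize unordered node pairs to (min, max) rows
#' @noRd
canonical_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
}

# Numeric key for a canonical pair; n^2 stays far below 2^53 for any graph
# this package targets, so keys are exact doubles.
pair_key <- function(pairs, n) {
  (as.numeric(pairs[, 1L]) - 1) * n + as.numeric(pairs[, 2L])
}

# Elementwise activations and their derivatives in terms of the pre-activation.
act_forward <- function(x, activation) {
  switch(activation,
    elu = ifelse(x > 0, x, expm1(x)),
    relu = pmax(x, 0),
    tanh = tanh(x),
    stop("unknown activation: ", activation)
  )
}

act_grad <- function(x, activation) {
  switch(activation,
    elu = ifelse(x > 0, 1, exp(x)),
    relu = (x > 0) * 1,
    tanh = 1 - tanh(x)^2,
    stop("unknown activation: ", activation)
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Inverted-dropout mask: zeros with probability `rate`, survivors scaled by
# 1/(1-rate) so expectations match eval mode.
dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}
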