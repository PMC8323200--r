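#' Logistic sigmoid
#' @param x numeric vector or matrix
#' @return values in (0, 1)
#' @keywords internal
#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rectified linear activation
#' @noRd
relu <- function(x) pmax(x, 0)

#' Evaluate code under a temporary RNG seed, restoring global RNG state.
#'
#' All randomised operations in the package (splits, initialisation, corpus
#' generation, shuffling) run through this so callers' RNG streams are never
#' disturbed and results are reproducible from the seed alone.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# row-wise L2 norms
row_norms <- function(m) sqrt(rowSums(m * m))

`%||%` <- function(a, b) if (is.null(a)) b else a
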