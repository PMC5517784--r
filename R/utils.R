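`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed on the log scale.
#' The multiplicative error model used throughout this package makes the
#' geometric (not arithmetic) mean the natural summary for intensities.
#'
#' @param x numeric vector of strictly positive values.
#' @return a single positive number.
#' @export
geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("geomean() requires finite, strictly positive values")
  exp(mean(log(x)))
}

# Dense ranking (1,1,2,...) used for stability tables: tied values share a
# rank and the next distinct value takes the next integer.
dense_rank <- function(x) match(x, sort(unique(x)))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
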