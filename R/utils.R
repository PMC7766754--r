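#' @useDynLib squigglesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif qnorm pnorm plogis sd cor fft coef predict residuals fitted simulate setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (draws advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

check_numeric_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L)
    stop_input(name, " must be a non-empty numeric vector")
  if (any(!is.finite(x)))
    stop_input(name, " contains non-finite values")
  invisible(x)
}
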