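#' @useDynLib stcpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef convolve fft lm median optim rnorm runif sd
#'   setNames spline t.test var complete.cases pt qnorm
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  x
}

check_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) stopf("'%s' must be >= 0", name)
  x
}

check_count <- function(x, name, min = 1L) {
  check_num(x, name)
  if (x != round(x) || x < min) stopf("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

## Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
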