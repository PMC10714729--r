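#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rlnorm rpois runif sd median dnorm coefficients
#'   t.test weighted.mean
#' @importFrom utils packageVersion write.csv
NULL

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched.  All stochastic operations in the package funnel through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Reflect (symmetric, edge-repeating) index lookup: for an axis of length n,
# maps out-of-range indices back into 1..n as  ...c b a | a b c ... | c b a...
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
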