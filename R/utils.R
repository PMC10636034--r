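#' @useDynLib fracctrl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef runif setNames
#' @importFrom utils combn read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their seed through this so
# that library calls never clobber the user's random stream.
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
  force(code)
}

# Derive a child seed from a base seed; kept within 32-bit signed range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k)) %% 2147483647)
}

stop2 <- function(...) stop(..., call. = FALSE)
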