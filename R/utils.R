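#' @importFrom stats coef lm glm binomial pnorm pt qnorm qlogis plogis rnorm
#'   runif rbinom rlogis sd var complete.cases p.adjust vcov predict
#'   setNames quantile
#' @importFrom utils head write.table read.delim
NULL

# linear voxel index from integer coordinates (1-based, x fastest)
voxel_index <- function(x, y, z, dim) {
  x + (y - 1L) * dim[1L] + (z - 1L) * dim[1L] * dim[2L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

# run `expr` under a private RNG stream; never touches the caller's RNG
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}
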