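#' @importFrom stats rnorm runif rbinom rnbinom plogis qlogis setNames
#' @importFrom methods is
#' @importFrom utils write.csv read.csv modifyList head
NULL

# numerical floor/ceiling for probabilities entering a log()
PROB_EPS <- 1e-7

clamp_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

sigmoid <- function(x) plogis(x)

softmax_rows <- function(a) {
  a <- a - apply(a, 1L, max)
  e <- exp(a)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# dense numeric matrix from a base or Matrix-package matrix
as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else x
}

is_binary_matrix <- function(x) {
  v <- if (is(x, "sparseMatrix")) x@x else as.vector(as_dense(x))
  all(v == 0 | v == 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
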