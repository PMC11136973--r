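## Small shared helpers: seed substreams, RNG-scoped evaluation, order
## statistics used across modules.

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' Every stochastic operation in the package draws its randomness from a
#' named substream of a single user-supplied integer seed, so that
#' individual pipeline stages are reproducible in isolation.
#'
#' @param seed Integer master seed.
#' @param name Character scalar naming the substream (e.g. `"umi_sampling"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # cheap deterministic string hash (polynomial rolling, mod a prime < 2^31)
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Lower median
#'
#' The element at position `ceiling(n / 2)` of the sorted vector: for an odd
#' number of values this is the usual median, for an even number it is the
#' lower of the two central values, so the median is always an attained
#' value.  Used for the per-gene across-cluster normalization of fold
#' changes, so that a fold change of exactly 1 is realized by an actual
#' cluster.
#'
#' @param x Numeric vector (length >= 1, no NAs).
#' @return A single numeric value.
#' @export
lower_median <- function(x) {
  n <- length(x)
  stopifnot(n >= 1L, !anyNA(x))
  sort(x, partial = ceiling(n / 2))[ceiling(n / 2)]
}

#' Adjusted Rand Index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' label renaming), ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## internal: stop() with a consistent parameter-error class
param_error <- function(msg) {
  stop(errorCondition(msg, class = c("mcatlas_param_error", "error")))
}

input_error <- function(msg) {
  stop(errorCondition(msg, class = c("mcatlas_input_error", "error")))
}
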