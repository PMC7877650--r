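#' @useDynLib fractalpp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans hclust cutree dist prcomp runif rnorm rpois sd var quantile lm coef
#' @importFrom utils read.csv head
NULL

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# squared Euclidean cross-distances between the rows of a and b
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# index of nearest row of b for each row of a
nearest_row <- function(a, b) max.col(-cross_dist2(a, b), ties.method = "first")
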