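#' Local growth curves: per-point neighbor counts over a radius grid
#'
#' The local growth curve of a point is the vector
#' \eqn{N(x, y, R_1), \dots, N(x, y, R_d)} of *other* points within the
#' closed ball of each radius. Stacked over all points it is an n x d
#' count matrix — the feature space in which the pattern is embedded for
#' clustering. Counting uses a uniform-grid spatial index (C++); the exact
#' all-pairs equivalent is available as the test oracle
#' [lgc_bruteforce()].
#'
#' @param pattern a [point_pattern()] with n >= 2
#' @param radii a [make_radius_grid()] or increasing numeric vector
#' @return object of class `growth_curve_matrix`: `counts` (n x d integer
#'   matrix, columns `R1..Rd`), `radii`, `point_ids`
#' @export
build_lgc <- function(pattern, radii) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2) stopf("local growth curves need at least 2 points")
  radii <- as_radius_grid(radii)
  counts <- cpp_radius_counts(pattern$coords[, 1], pattern$coords[, 2],
                              radii$radii)
  colnames(counts) <- paste0("R", seq_len(radii$d))
  structure(list(counts = counts, radii = radii,
                 point_ids = seq_len(pattern$n)),
            class = "growth_curve_matrix")
}

#' All-pairs reference implementation of the growth-curve counts
#'
#' Computes the same n x d matrix as [build_lgc()] from the full distance
#' matrix. Quadratic in n; intended as an independent oracle for small
#' patterns.
#'
#' @inheritParams build_lgc
#' @return integer matrix n x d
#' @export
lgc_bruteforce <- function(pattern, radii) {
  stopifnot(inherits(pattern, "point_pattern"))
  radii <- as_radius_grid(radii)
  dm <- as.matrix(dist(pattern$coords))
  diag(dm) <- Inf
  out <- vapply(radii$radii, function(r) rowSums(dm <= r), numeric(pattern$n))
  out <- matrix(as.integer(out), pattern$n, radii$d)
  colnames(out) <- paste0("R", seq_len(radii$d))
  out
}

#' @export
print.growth_curve_matrix <- function(x, ...) {
  cat(sprintf("growth_curve_matrix: %d points x %d radii [%g .. %g]\n",
              nrow(x$counts), x$radii$d, min(x$radii$radii), max(x$radii$radii)))
  invisible(x)
}

#' Local fractal dimension field
#'
#' Per point, the OLS slope of \eqn{\log N(R)} vs \eqn{\log R} over the
#' radii where the count is at least 1 — the local analogue of the sandbox
#' dimension. Zero counts are dropped from the fit (not offset), the same
#' masking policy as the global sandbox fit. Points with fewer than 3
#' usable radii are flagged invalid rather than given a spurious value;
#' locally the slope may legitimately exceed the embedding dimension 2.
#'
#' @param lgc a [build_lgc()] result
#' @param min_radii minimum usable radii for a valid fit (default 3)
#' @return object of class `local_dimension_field`: `fdim` (length-n,
#'   NA where invalid), `valid` (logical mask), `n_used` per point
#' @export
local_fdim <- function(lgc, min_radii = 3L) {
  stopifnot(inherits(lgc, "growth_curve_matrix"))
  counts <- lgc$counts
  n <- nrow(counts); d <- ncol(counts)
  lr <- log(lgc$radii$radii)
  M <- counts >= 1L
  Y <- log(pmax(counts, 1L))      # masked-out entries contribute 0 below
  X <- matrix(lr, n, d, byrow = TRUE)
  k <- rowSums(M)
  sx <- rowSums(X * M); sy <- rowSums(Y * M)
  sxx <- rowSums(X * X * M); sxy <- rowSums(X * Y * M)
  denom <- k * sxx - sx^2
  slope <- (k * sxy - sx * sy) / denom
  valid <- k >= min_radii & denom > 0 & is.finite(slope)
  slope[!valid] <- NA_real_
  structure(list(fdim = slope, valid = valid, n_used = as.integer(k)),
            class = "local_dimension_field")
}

#' @export
print.local_dimension_field <- function(x, ...) {
  v <- x$fdim[x$valid]
  cat(sprintf("local_dimension_field: %d/%d valid, mean fDim %.3f (sd %.3f)\n",
              sum(x$valid), length(x$valid), mean(v), sd(v)))
  invisible(x)
}

#' Preprocess growth curves into a clustering feature matrix
#'
#' Raw growth-curve counts span orders of magnitude across radii, so
#' Euclidean clustering of raw counts is dominated by the largest radii.
#' The default transform is `log1p` followed by per-feature z-scoring.
#' Constant columns are dropped under z-scoring (with a warning) since
#' they carry no information and would divide by zero.
#'
#' @param lgc a [build_lgc()] result, or a plain numeric matrix of features
#' @param transform one of `"log1p+zscore"` (default), `"log1p"`,
#'   `"zscore"`, `"raw"`
#' @return object of class `feature_matrix`: `values` (n x p, finite),
#'   `transform`, `feature_names`, `dropped` (names of removed columns)
#' @export
preprocess <- function(lgc, transform = c("log1p+zscore", "log1p", "zscore", "raw")) {
  transform <- match.arg(transform)
  values <- if (inherits(lgc, "growth_curve_matrix")) lgc$counts else as.matrix(lgc)
  if (is.null(colnames(values))) colnames(values) <- paste0("V", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stopf("non-finite feature values before preprocessing")
  if (transform %in% c("log1p", "log1p+zscore")) values <- log1p(values)
  dropped <- character(0)
  if (transform %in% c("zscore", "log1p+zscore")) {
    sds <- apply(values, 2, sd)
    if (any(sds == 0)) {
      dropped <- colnames(values)[sds == 0]
      warnf("dropping %d zero-variance feature(s) under z-scoring: %s",
            length(dropped), paste(dropped, collapse = ", "))
      values <- values[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    values <- scale(values, center = TRUE, scale = sds)
    attr(values, "scaled:center") <- NULL
    attr(values, "scaled:scale") <- NULL
  }
  structure(list(values = values, transform = transform,
                 feature_names = colnames(values), dropped = dropped),
            class = "feature_matrix")
}

as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values
  else if (inherits(x, "growth_curve_matrix")) {
    v <- x$counts; storage.mode(v) <- "double"; v
  } else as.matrix(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d x %d (%s)%s\n", nrow(x$values), ncol(x$values),
              x$transform,
              if (length(x$dropped)) sprintf(", %d dropped", length(x$dropped)) else ""))
  invisible(x)
}

#' PCA variance summary of a feature matrix
#'
#' Fraction of variance explained per principal component of the
#' (centered) features — the linear-redundancy companion to the
#' Morisita-based intrinsic dimension: strongly redundant growth-curve
#' features concentrate the variance in the first few components.
#'
#' @param features a [preprocess()] result or numeric matrix (n > p >= 2)
#' @return object of class `pca_summary`: `explained_fraction` (sums
#'   to 1), `cumulative` (non-decreasing to 1), `sdev`
#' @export
pca_summary <- function(features) {
  v <- as_feature_values(features)
  if (ncol(v) < 2) stopf("PCA summary needs at least 2 features")
  if (nrow(v) <= ncol(v)) stopf("PCA summary needs n > p")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  varprop <- pc$sdev^2 / sum(pc$sdev^2)
  # pad with exact zeros when prcomp returns fewer than p components
  if (length(varprop) < ncol(v)) varprop <- c(varprop, rep(0, ncol(v) - length(varprop)))
  structure(list(explained_fraction = varprop, cumulative = cumsum(varprop),
                 sdev = pc$sdev),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  k90 <- which(x$cumulative >= 0.9)[1]
  cat(sprintf("pca_summary: %d components, first explains %.1f%%, %d reach 90%%\n",
              length(x$explained_fraction), 100 * x$explained_fraction[1], k90))
  invisible(x)
}
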