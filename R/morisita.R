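#' Multipoint Morisita index across grid resolutions
#'
#' For each cell edge \eqn{\delta}, the unit hypercube of (min-max
#' rescaled) features is partitioned into \eqn{Q = (1/\delta)^E} cells,
#' the points per cell \eqn{n_i} are counted, and the index of order m is
#' \deqn{I_{m,\delta} = Q^{m-1}
#'   \frac{\sum_i n_i (n_i-1) \cdots (n_i-m+1)}{N (N-1) \cdots (N-m+1)}.}
#' It is about 1 for a random pattern, above 1 for clustered and below 1
#' for regular (structured) patterns. Cells are half-open with the last
#' cell closed, so a point exactly on the upper boundary belongs to the
#' last cell. The \eqn{Q^{m-1}} factor is carried in log space (it
#' overflows double precision long before the log does).
#'
#' @param data numeric matrix n x E (rows = observations); rescaled to
#'   the unit cube per feature internally
#' @param m index order (>= 2)
#' @param deltas cell edge lengths, each an inverse integer in (0, 1];
#'   default \eqn{1/2, 1/4, \dots, 1/2^5}
#' @param rescale min-max rescale each feature to `[0, 1]` before
#'   gridding (default TRUE; set FALSE when the data already live in the
#'   unit cube and the absolute cell layout matters)
#' @return object of class `morisita_curve`: `m`, `deltas`, `Q`,
#'   `values` (the \eqn{I_{m,\delta}}), `cell_counts` (list of occupied
#'   cell counts per delta, kept for audit), `occupancy` (mean points per
#'   occupied cell)
#' @export
morisita_index <- function(data, m = 2L, deltas = 2^-(1:5), rescale = TRUE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n <- nrow(data); E <- ncol(data)
  if (m < 2) stopf("Morisita order m must be >= 2")
  if (n < m) stopf("need at least m = %d points (got %d)", m, n)
  if (length(deltas) == 0) stopf("empty delta list")
  inv <- 1 / deltas
  if (any(abs(inv - round(inv)) > 1e-8))
    stopf("each delta must divide the unit interval (1/delta integer)")
  u <- if (rescale) unit_rescale(data) else {
    if (any(data < 0) || any(data > 1))
      stopf("with rescale = FALSE the data must already lie in the unit cube")
    data
  }
  lfallN <- sum(log(n - seq_len(m) + 1))   # log N(N-1)...(N-m+1)
  res <- lapply(deltas, function(del) {
    ncell <- round(1 / del)
    cells <- floor(u / del)
    cells[cells >= ncell] <- ncell - 1     # last cell closed
    key <- do.call(paste, c(as.data.frame(cells), sep = ","))
    ni <- as.integer(table(key))
    big <- ni[ni >= m]
    S <- if (length(big)) {
      sum(vapply(big, function(v) exp(sum(log(v - seq_len(m) + 1))), numeric(1)))
    } else 0
    I <- if (S > 0) exp((m - 1) * E * log(ncell) + log(S) - lfallN) else 0
    list(I = I, ni = ni, Q = ncell^E)
  })
  structure(list(
    m = as.integer(m), deltas = deltas,
    Q = vapply(res, `[[`, numeric(1), "Q"),
    values = vapply(res, `[[`, numeric(1), "I"),
    cell_counts = lapply(res, `[[`, "ni"),
    occupancy = vapply(res, function(r) mean(r$ni), numeric(1))
  ), class = "morisita_curve")
}

unit_rescale <- function(data) {
  rng <- apply(data, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1                      # constant feature -> all cells 0
  sweep(sweep(data, 2, rng[1, ]), 2, span, "/")
}

#' @export
print.morisita_curve <- function(x, ...) {
  cat(sprintf("morisita_curve (m = %d):\n", x$m))
  print(data.frame(delta = x$deltas, I = x$values, occupancy = x$occupancy))
  invisible(x)
}

#' Morisita-based intrinsic dimension
#'
#' The intrinsic dimension (ID) of data embedded in an E-dimensional
#' feature space is recovered from the scaling of the m-Morisita index
#' across cell sizes: with \eqn{S_m} the OLS slope of
#' \eqn{\log I_{m,\delta}} vs \eqn{\log \delta},
#' \deqn{ID = E + S_m / (m - 1).}
#' For data uniform on a d-dimensional manifold the index scales as
#' \eqn{\delta^{(d-E)(m-1)}}, so the estimator recovers d; in particular
#' uniform data in the full cube has slope about 0 and ID about E.
#' Deltas where the index is zero are dropped; among the two finest
#' scales, deltas where the mean occupancy of the occupied cells falls
#' below m (too sparse for a stable falling factorial) are excluded from
#' the fit window as well.
#'
#' @inheritParams morisita_index
#' @return object of class `id_estimate`: `id_value`, `E`, `slope`, `m`,
#'   `curve` (the underlying [morisita_index()] result), `used` (fit mask)
#' @export
estimate_id <- function(data, m = 2L, deltas = 2^-(1:5)) {
  data <- as.matrix(data)
  E <- ncol(data)
  curve <- morisita_index(data, m = m, deltas = deltas)
  used <- curve$values > 0
  finest <- order(curve$deltas)[seq_len(min(2L, length(deltas)))]
  used[finest] <- used[finest] & curve$occupancy[finest] >= m
  if (sum(used) < 3)
    stopf("fewer than 3 usable cell sizes for the ID fit (have %d); use coarser deltas or more data",
          sum(used))
  fit <- fit_loglog(curve$deltas, curve$values, extra_mask = used)
  id <- E + fit$slope / (m - 1)
  structure(list(id_value = id, E = E, slope = fit$slope, m = as.integer(m),
                 curve = curve, used = fit$used_mask, fit = fit),
            class = "id_estimate")
}

#' @export
print.id_estimate <- function(x, ...) {
  cat(sprintf("id_estimate: ID = %.3f (E = %d, m = %d, slope %.3f, %d deltas used)\n",
              x$id_value, x$E, x$m, x$slope, sum(x$used)))
  invisible(x)
}

#' Morisita-based redundancy reduction (greedy feature ranking)
#'
#' Ranks features by their contribution to the intrinsic dimension of the
#' selected subset: starting from the empty set, at each step the feature
#' maximizing the ID of the enlarged subset is appended (ties broken by
#' lowest feature index). Features whose best achievable ID gain falls
#' below `threshold` are considered redundant; `selected` is the prefix of
#' the ranking up to the first sub-threshold gain. An exact duplicate of
#' an already-selected feature adds no degrees of freedom, so it gains
#' (approximately) zero ID and is discarded.
#'
#' @param features a [preprocess()] result or numeric matrix (p >= 1)
#' @param m Morisita order (default 2)
#' @param threshold minimal ID gain to keep a feature (default 0.05)
#' @param deltas cell sizes passed to [estimate_id()]
#' @param max_rank stop ranking after this many features (default all);
#'   useful when p is large and only the selected prefix matters
#' @return object of class `feature_ranking`: `order` (feature names in
#'   greedy order), `id_trace` (ID after each addition), `selected`,
#'   `threshold`
#' @export
rank_redundancy <- function(features, m = 2L, threshold = 0.05,
                            deltas = 2^-(1:5), max_rank = NULL) {
  v <- as_feature_values(features)
  p <- ncol(v)
  if (p < 1) stopf("need at least one feature")
  if (is.null(colnames(v))) colnames(v) <- paste0("V", seq_len(p))
  max_rank <- min(max_rank %||% p, p)
  remaining <- seq_len(p)
  chosen <- integer(0)
  trace <- numeric(0)
  while (length(remaining) > 0 && length(chosen) < max_rank) {
    ids <- vapply(remaining, function(j) {
      sub <- v[, c(chosen, j), drop = FALSE]
      tryCatch(estimate_id(sub, m = m, deltas = deltas)$id_value,
               error = function(e) -Inf)
    }, numeric(1))
    best <- which(ids == max(ids))[1]      # tie -> lowest feature index
    chosen <- c(chosen, remaining[best])
    trace <- c(trace, ids[best])
    remaining <- remaining[-best]
  }
  if (!length(trace) || !is.finite(trace[1]))
    stopf("intrinsic dimension could not be estimated for any single feature")
  gains <- diff(c(0, trace))
  keep <- 1L
  for (i in seq_along(gains)[-1]) {
    if (gains[i] < threshold) break
    keep <- i
  }
  structure(list(order = colnames(v)[chosen], order_idx = chosen,
                 id_trace = trace,
                 selected = colnames(v)[chosen[seq_len(keep)]],
                 selected_idx = chosen[seq_len(keep)],
                 threshold = threshold, m = as.integer(m)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking: %d ranked, %d selected (threshold %g)\n",
              length(x$order), length(x$selected), x$threshold))
  cat("  order:   ", paste(x$order, collapse = " "), "\n")
  cat("  id_trace:", paste(sprintf("%.2f", x$id_trace), collapse = " "), "\n")
  cat("  selected:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}
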