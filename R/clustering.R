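#' Hopkins statistic for clustering tendency
#'
#' Compares nearest-neighbor distances of `sample` uniformly generated
#' points in the feature bounding box (to the data) with nearest-neighbor
#' distances of `sample` sampled data points (to the rest of the data):
#' \eqn{H = \sum u / (\sum u + \sum w)}. For spatially random data H is
#' about 0.5; it approaches 1 for clustered data. Verdict convention:
#' `clusterable` when H > 0.7, `uniform` when H <= 0.6, `ambiguous`
#' between.
#'
#' @param features a [preprocess()] result or numeric matrix
#' @param sample number of probe points (n must be at least twice this)
#' @param seed integer seed
#' @return object of class `clusterability_report`: `hopkins`,
#'   `n_sampled`, `verdict`, `seed`
#' @export
hopkins_stat <- function(features, sample = 100L, seed = NULL) {
  v <- as_feature_values(features)
  n <- nrow(v)
  if (n < 2 * sample)
    stopf("Hopkins statistic needs n >= 2*sample (n = %d, sample = %d)", n, sample)
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  if (any(hi - lo <= 0)) stopf("degenerate feature bounding box")
  with_seed(seed, {
    idx <- sample.int(n, sample)
    U <- vapply(seq_len(ncol(v)), function(j) runif(sample, lo[j], hi[j]),
                numeric(sample))
    if (sample == 1) U <- matrix(U, 1)
    u <- sqrt(apply(cross_dist2(U, v), 1, min))
    d2 <- cross_dist2(v[idx, , drop = FALSE], v)
    d2[cbind(seq_len(sample), idx)] <- Inf       # exclude self
    w <- sqrt(apply(d2, 1, min))
    H <- sum(u) / (sum(u) + sum(w))
    verdict <- if (H > 0.7) "clusterable" else if (H <= 0.6) "uniform" else "ambiguous"
    structure(list(hopkins = H, n_sampled = as.integer(sample),
                   verdict = verdict, seed = seed),
              class = "clusterability_report")
  })
}

#' @export
print.clusterability_report <- function(x, ...) {
  cat(sprintf("Hopkins statistic: %.3f (%s, %d probes)\n",
              x$hopkins, x$verdict, x$n_sampled))
  invisible(x)
}

new_assignment <- function(labels, centers, method, seed = NULL, extra = list()) {
  labels <- as.integer(labels)
  k <- max(labels)
  if (any(tabulate(labels, k) == 0L)) {
    # renumber so every cluster is non-empty
    present <- sort(unique(labels))
    labels <- match(labels, present)
    centers <- centers[present, , drop = FALSE]
    k <- length(present)
  }
  structure(c(list(labels = labels, k = k, centers_or_medoids = centers,
                   method = method, seed = seed), extra),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): k = %d, sizes %s\n", x$method, x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling proportionally to squared distance from the current center set.
kmeanspp_centers <- function(v, k) {
  n <- nrow(v)
  centers <- matrix(NA_real_, k, ncol(v))
  i <- sample.int(n, 1)
  centers[1, ] <- v[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(v, 2, centers[1, ])^2)
    for (j in 2:k) {
      i <- if (sum(d2) > 0) sample.int(n, 1, prob = d2 / sum(d2))
      else sample.int(n, 1)     # all points already coincide with a center

      centers[j, ] <- v[i, ]
      d2 <- pmin(d2, rowSums(sweep(v, 2, centers[j, ])^2))
    }
  }
  centers
}

#' k-means clustering with k-means++ seeding
#'
#' Lloyd iterations from k-means++ starts; `nstart` restarts, best total
#' within-cluster sum of squares kept. Deterministic under a fixed seed.
#'
#' @param features a [preprocess()] result or numeric matrix
#' @param k number of clusters (2 <= k < n; k = 1 allowed for baselines)
#' @param seed integer seed
#' @param nstart restarts (default 10)
#' @return a `cluster_assignment` (`labels` in 1..k, `centers_or_medoids`
#'   the k centroids, `inertia` the best within-SS)
#' @export
cluster_kmeans <- function(features, k, seed = NULL, nstart = 10L) {
  v <- as_feature_values(features)
  if (k >= nrow(v)) stopf("k must be smaller than the number of points")
  if (k < 1) stopf("k must be >= 1")
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      init <- kmeanspp_centers(v, k)
      km <- tryCatch(suppressWarnings(
        kmeans(v, centers = init, iter.max = 100L, algorithm = "Lloyd")),
        error = function(e) NULL)   # duplicate rows can make ++ centers collide
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    if (is.null(best))
      stopf("k-means failed for k = %d (fewer than k distinct points?)", k)
    new_assignment(best$cluster, best$centers, "kmeans", seed,
                   extra = list(inertia = best$tot.withinss))
  })
}

#' PAM (partitioning around medoids)
#'
#' k-medoids by BUILD + SWAP on Euclidean dissimilarities via
#' [cluster::pam()]: cluster centers are actual data rows (medoids), which
#' makes the centers directly interpretable as representative curves. PAM
#' is O(n^2); inputs beyond `max_n` are refused with a pointer to
#' [cluster_clara()].
#'
#' @inheritParams cluster_kmeans
#' @param max_n guard on the quadratic cost (default 10000)
#' @return a `cluster_assignment` with `medoid_ids` (row indices) and
#'   `objective` (pam's build/swap objective values)
#' @export
cluster_pam <- function(features, k, seed = NULL, max_n = 10000L) {
  v <- as_feature_values(features)
  n <- nrow(v)
  if (k >= n) stopf("k must be smaller than the number of points")
  if (n > max_n) stopf("PAM is quadratic in n; use cluster_clara() for n > %d", max_n)
  pm <- cluster::pam(v, k, metric = "euclidean", pamonce = 5)
  new_assignment(pm$clustering, v[pm$id.med, , drop = FALSE], "pam", seed,
                 extra = list(medoid_ids = pm$id.med, objective = pm$objective))
}

#' CLARA (clustering large applications)
#'
#' k-medoids for large n: PAM is run on `n_samples` subsamples of size
#' `sample_size`; after the first draw every subsample is forced to
#' contain the best medoid set found so far; the medoid set minimizing the
#' total dissimilarity over *all* points wins, and every point is assigned
#' to its nearest medoid. Defaults follow the classical convention of 5
#' draws of size 40 + 2k.
#'
#' @inheritParams cluster_kmeans
#' @param n_samples number of subsamples (default 5)
#' @param sample_size subsample size (default 40 + 2k; clamped to n with a
#'   warning when larger)
#' @return a `cluster_assignment` with `medoid_ids` (row indices into the
#'   full data) and `avg_dissimilarity`
#' @export
cluster_clara <- function(features, k, n_samples = 5L, sample_size = NULL,
                          seed = NULL) {
  v <- as_feature_values(features)
  n <- nrow(v)
  if (k >= n) stopf("k must be smaller than the number of points")
  sample_size <- sample_size %||% (40L + 2L * k)
  if (sample_size < k + 1) stopf("sample_size must be at least k + 1")
  if (sample_size > n) {
    warnf("sample_size %d > n = %d; clamped to n", sample_size, n)
    sample_size <- n
  }
  with_seed(seed, {
    best_med <- NULL; best_cost <- Inf
    for (s in seq_len(n_samples)) {
      base <- if (is.null(best_med)) integer(0) else best_med
      pool <- setdiff(seq_len(n), base)
      idx <- c(base, sample(pool, min(sample_size - length(base), length(pool))))
      pm <- cluster::pam(v[idx, , drop = FALSE], k, metric = "euclidean",
                         pamonce = 5)
      med <- idx[pm$id.med]
      cost <- sum(sqrt(apply(cross_dist2(v, v[med, , drop = FALSE]), 1, min)))
      if (cost < best_cost) { best_cost <- cost; best_med <- med }
    }
    labels <- nearest_row(v, v[best_med, , drop = FALSE])
    new_assignment(labels, v[best_med, , drop = FALSE], "clara", seed,
                   extra = list(medoid_ids = best_med,
                                avg_dissimilarity = best_cost / n))
  })
}

#' Hierarchical clustering of (sub)sampled features
#'
#' Euclidean distance, average linkage by default. The O(n^2) distance
#' matrix restricts this to moderate n; larger inputs must be subsampled
#' by the caller (the error says so).
#'
#' @param features a [preprocess()] result or numeric matrix, n <= `max_n`
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`)
#' @param max_n guard (default 10000)
#' @return object of class `linkage_result`: `merge`, `height`,
#'   `leaf_order`, `linkage`, plus the underlying `hclust` object
#' @export
cluster_hierarchical <- function(features, linkage = "average", max_n = 10000L) {
  v <- as_feature_values(features)
  if (nrow(v) > max_n)
    stopf("hierarchical clustering limited to n <= %d; subsample first", max_n)
  hc <- hclust(dist(v), method = linkage)
  structure(list(merge = hc$merge, height = hc$height, leaf_order = hc$order,
                 linkage = linkage, hclust = hc, n = nrow(v)),
            class = "linkage_result")
}

#' Cut a dendrogram into a cluster assignment
#'
#' @param linkres a [cluster_hierarchical()] result
#' @param k number of clusters
#' @param features the features the tree was built on (for cluster means)
#' @return a `cluster_assignment` (centers are cluster means)
#' @export
cut_dendrogram <- function(linkres, k, features) {
  stopifnot(inherits(linkres, "linkage_result"))
  v <- as_feature_values(features)
  labels <- cutree(linkres$hclust, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(v[labels == c, , drop = FALSE])))
  new_assignment(labels, centers, paste0("hclust-", linkres$linkage))
}

# ---- internal validity indices -------------------------------------------

within_ss <- function(v, labels) {
  sum(vapply(unique(labels), function(c) {
    m <- v[labels == c, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
}

calinski_harabasz <- function(v, labels) {
  n <- nrow(v); k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  g <- colMeans(v)
  bss <- sum(vapply(unique(labels), function(c) {
    m <- v[labels == c, , drop = FALSE]
    nrow(m) * sum((colMeans(m) - g)^2)
  }, numeric(1)))
  wss <- within_ss(v, labels)
  (bss / (k - 1)) / (wss / (n - k))
}

davies_bouldin <- function(v, labels) {
  cl <- sort(unique(labels)); k <- length(cl)
  if (k < 2) return(NA_real_)
  cent <- do.call(rbind, lapply(cl, function(c) colMeans(v[labels == c, , drop = FALSE])))
  s <- vapply(seq_len(k), function(i) {
    m <- v[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cent[i, ])^2)))
  }, numeric(1))
  dcent <- as.matrix(dist(cent))
  mean(vapply(seq_len(k), function(i) {
    r <- (s[i] + s[-i]) / dcent[i, -i]
    max(r)
  }, numeric(1)))
}

mean_silhouette <- function(v, labels, max_n = 2000L, seed = NULL) {
  n <- nrow(v)
  if (n > max_n) {
    idx <- with_seed(seed, sample.int(n, max_n))
    v <- v[idx, , drop = FALSE]; labels <- labels[idx]
    if (length(unique(labels)) < 2) return(NA_real_)
  }
  sil <- cluster::silhouette(labels, dist(v))
  mean(sil[, "sil_width"])
}

#' Cluster-number voting over internal validity indices
#'
#' Fixes one clustering method, clusters at every k in `k_range`, scores
#' each partition with a set of internal validity indices, lets each
#' index vote for its best k, and takes the majority (ties broken toward
#' the smallest k). Implemented indices: mean silhouette width (max),
#' Calinski-Harabasz (max), Davies-Bouldin (min), gap statistic with B
#' uniform reference sets (first-SE-max rule, falling back to the argmax
#' of the gap), and the within-SS elbow (max second difference). An index
#' failing at some k forfeits its vote with a warning.
#'
#' @param features a [preprocess()] result or numeric matrix
#' @param k_range candidate cluster counts (subset of 2..n-1)
#' @param method clustering method used for every k: `"kmeans"` (default),
#'   `"pam"` or `"clara"`
#' @param seed integer seed
#' @param B number of uniform reference datasets for the gap statistic
#' @return object of class `kvote_report`: `k_range`, `index_votes`
#'   (named vector), `majority_k`, `scores` (per-index per-k table),
#'   `assignments` (one per k, reusable by the caller)
#' @export
vote_k <- function(features, k_range = 2:8, method = c("kmeans", "pam", "clara"),
                   seed = NULL, B = 10L) {
  method <- match.arg(method)
  v <- as_feature_values(features)
  n <- nrow(v)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= n)) stopf("k_range must lie in [2, n-1]")
  cluster_at <- function(data, k, s) {
    switch(method,
      kmeans = cluster_kmeans(data, k, seed = s),
      pam = cluster_pam(data, k, seed = s),
      clara = cluster_clara(data, k, seed = s))
  }
  with_seed(seed, {
    seeds <- sample.int(2^30, length(k_range) + B)
    asg <- lapply(seq_along(k_range), function(i)
      tryCatch(cluster_at(v, k_range[i], seeds[i]), error = function(e) NULL))
    ok <- !vapply(asg, is.null, logical(1))
    if (any(!ok))
      warnf("clustering failed at k = %s; those k dropped from the vote",
            paste(k_range[!ok], collapse = ", "))
    k_range <- k_range[ok]; asg <- asg[ok]
    if (length(k_range) < 2) stopf("fewer than 2 candidate k values survived")
    labels <- lapply(asg, `[[`, "labels")
    wss <- vapply(labels, function(l) within_ss(v, l), numeric(1))

    scores <- list()
    votes <- c()
    vote_of <- function(name, vals, best = c("max", "min")) {
      best <- match.arg(best)
      scores[[name]] <<- vals
      if (all(is.na(vals))) {
        warnf("index '%s' failed at every k; vote skipped", name)
        return(invisible(NULL))
      }
      kk <- k_range[if (best == "max") which.max(vals) else which.min(vals)]
      votes[name] <<- kk
    }
    vote_of("silhouette",
            vapply(labels, function(l) tryCatch(
              mean_silhouette(v, l, seed = seeds[1]), error = function(e) NA_real_),
              numeric(1)), "max")
    vote_of("calinski_harabasz",
            vapply(labels, function(l) calinski_harabasz(v, l), numeric(1)), "max")
    vote_of("davies_bouldin",
            vapply(labels, function(l) davies_bouldin(v, l), numeric(1)), "min")

    # gap statistic: compare log W_k to its expectation under a uniform
    # box reference
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
    ref_lw <- matrix(NA_real_, B, length(k_range))
    for (b in seq_len(B)) {
      refv <- vapply(seq_len(ncol(v)), function(j) runif(n, lo[j], hi[j]), numeric(n))
      for (i in seq_along(k_range)) {
        ra <- cluster_at(refv, k_range[i], seeds[length(k_range) + b])
        ref_lw[b, i] <- log(within_ss(refv, ra$labels))
      }
    }
    gap <- colMeans(ref_lw) - log(pmax(wss, 1e-300))  # guard: exact-duplicate clusters
    se <- apply(ref_lw, 2, sd) * sqrt(1 + 1 / B)
    gap_k <- NA_integer_
    for (i in seq_along(k_range)[-length(k_range)]) {
      if (gap[i] >= gap[i + 1] - se[i + 1]) { gap_k <- k_range[i]; break }
    }
    if (is.na(gap_k)) gap_k <- k_range[which.max(gap)]
    scores[["gap"]] <- gap
    votes["gap"] <- gap_k

    # elbow: maximal positive second difference of W_k
    if (length(k_range) >= 3) {
      d2 <- diff(diff(wss))                 # W_{k-1} + W_{k+1} - 2 W_k, interior k
      votes["elbow"] <- k_range[which.max(d2) + 1L]
      scores[["elbow_wss"]] <- wss
    }

    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    majority_k <- min(winners)
    structure(list(k_range = k_range, index_votes = votes,
                   majority_k = majority_k,
                   scores = as.data.frame(c(list(k = k_range), scores)),
                   assignments = asg, method = method, seed = seed),
              class = "kvote_report")
  })
}

#' @export
print.kvote_report <- function(x, ...) {
  cat(sprintf("kvote_report (%s over k in %d..%d): majority k = %d\n",
              x$method, min(x$k_range), max(x$k_range), x$majority_k))
  print(x$index_votes)
  invisible(x)
}

# ---- self-organizing map --------------------------------------------------

som_grid_positions <- function(rows, cols, topology) {
  g <- expand.grid(col = seq_len(cols) - 1, row = seq_len(rows) - 1)
  x <- g$col; y <- g$row
  if (topology == "hexagonal") {
    x <- x + ifelse(g$row %% 2 == 1, 0.5, 0)
    y <- y * sqrt(3) / 2
  }
  cbind(x, y)
}

#' Train a self-organizing (Kohonen) map
#'
#' Classical online SOM: codebook vectors on a 2-D grid are initialized
#' uniformly within the per-feature data ranges and updated by
#' competition (best-matching unit), cooperation (Gaussian neighborhood
#' on the grid) and adaptation. The learning rate decays linearly from
#' 0.5 to 0.01 and the neighborhood radius from max(rows, cols)/2 to 1
#' over all presentations. The default 20 x 15 hexagonal grid suits
#' growth-curve feature spaces of some 10^4–10^5 curves; use smaller
#' grids for small data.
#'
#' @param features a [preprocess()] result or numeric matrix
#' @param rows,cols grid size (default 20 x 15)
#' @param topology `"hexagonal"` (default) or `"rectangular"`
#' @param epochs training epochs (default 100); each epoch presents every
#'   observation once in random order
#' @param seed integer seed (controls init and presentation order)
#' @return object of class `som_model`: `codebook`
#'   ((rows*cols) x p), `grid` (rows, cols, topology, unit positions),
#'   `training_log` (mean quantization error after each epoch), `seed`
#' @export
som_train <- function(features, rows = 20L, cols = 15L,
                      topology = c("hexagonal", "rectangular"),
                      epochs = 100L, seed = NULL) {
  topology <- match.arg(topology)
  v <- as_feature_values(features)
  if (epochs < 1) stopf("epochs must be >= 1")
  if (rows < 1 || cols < 1) stopf("grid must be at least 1 x 1")
  n <- nrow(v); p <- ncol(v); u <- rows * cols
  gridpos <- som_grid_positions(rows, cols, topology)
  with_seed(seed, {
    lo <- apply(v, 2, min); hi <- apply(v, 2, max)
    cb0 <- vapply(seq_len(p), function(j) runif(u, lo[j], hi[j]), numeric(u))
    if (u == 1) cb0 <- matrix(cb0, 1)
    ord <- unlist(lapply(seq_len(epochs), function(e) sample.int(n))) - 1L
    fit <- cpp_som_train(v, cb0, gridpos, ord, as.integer(epochs),
                         0.5, 0.01, max(rows, cols) / 2, 1.0)
    colnames(fit$codebook) <- colnames(v)
    structure(list(codebook = fit$codebook,
                   grid = list(rows = rows, cols = cols, topology = topology,
                               positions = gridpos),
                   training_log = as.numeric(fit$qe),
                   epochs = as.integer(epochs), seed = seed),
              class = "som_model")
  })
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d %s grid, %d epochs, final QE %.4f\n",
              x$grid$rows, x$grid$cols, x$grid$topology, x$epochs,
              x$training_log[x$epochs]))
  invisible(x)
}

#' Best-matching unit of each observation
#'
#' @param model a [som_train()] result
#' @param features features mapped through the codebook
#' @return integer vector of unit indices (1..rows*cols)
#' @export
som_bmu <- function(model, features) {
  stopifnot(inherits(model, "som_model"))
  nearest_row(as_feature_values(features), model$codebook)
}

#' Cluster data through a trained SOM
#'
#' Two-stage clustering: the codebook vectors are clustered into k groups
#' (k-means by default, or average-linkage hierarchical), and every
#' observation inherits the cluster of its best-matching unit. Empty
#' clusters (codebook groups matched by no observation) are renumbered
#' away.
#'
#' @param model a [som_train()] result
#' @param features the observations to label
#' @param k number of clusters
#' @param method `"kmeans"` (default) or `"hierarchical"`
#' @param seed integer seed for the codebook clustering
#' @return a `cluster_assignment` (centers are codebook-cluster means)
#' @export
som_cluster <- function(model, features, k, method = c("kmeans", "hierarchical"),
                        seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "som_model"))
  cb <- model$codebook
  if (nrow(cb) < k) stopf("grid has fewer units (%d) than clusters (%d)", nrow(cb), k)
  cb_labels <- if (method == "kmeans") {
    cluster_kmeans(cb, k, seed = seed)$labels
  } else {
    cutree(hclust(dist(cb), method = "average"), k = k)
  }
  bmu <- som_bmu(model, features)
  labels <- cb_labels[bmu]
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(c)
    colMeans(cb[cb_labels == c, , drop = FALSE])))
  new_assignment(labels, centers, paste0("som+", method), seed,
                 extra = list(bmu = bmu))
}
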