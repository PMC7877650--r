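#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis in one serializable
#' object, so a run is reproducible from its echoed configuration.
#'
#' @param points path to a points CSV (columns x, y), or a
#'   [point_pattern()] object
#' @param domain optional GeoJSON path or [validity_domain()]
#' @param r_min,r_max,d,spacing radius-grid parameters (defaults: the
#'   300–10000 length-unit range with d = 25, geometric)
#' @param radii optional explicit radius vector overriding
#'   `r_min`/`r_max`/`d` (useful when specific scales must be probed or
#'   avoided)
#' @param transform feature transform for clustering (see [preprocess()])
#' @param method clustering method: `"clara"` (default), `"kmeans"`,
#'   `"pam"`, `"hierarchical"`, `"som"`
#' @param k number of clusters, or `"vote"` to decide by index voting
#' @param k_range candidate k values when voting
#' @param redundancy run Morisita-based redundancy reduction and the
#'   full-vs-reduced comparison
#' @param csr_reference also generate and analyze a CSR reference of equal
#'   n in the domain (requires `domain`)
#' @param profile_radius profiling radius for cluster interpretation
#'   (default 4000 length units, snapped to the nearest grid radius)
#' @param morisita_m,id_deltas Morisita order and cell sizes
#' @param max_index_n subsample size for the quadratic-cost steps
#'   (hierarchical heatmap ordering, silhouette), default 5000
#' @param seed integer seed driving every random stage
#' @param out_dir artifact directory (created; default `tempfile()`)
#' @return object of class `run_config`
#' @export
run_config <- function(points, domain = NULL,
                       r_min = 300, r_max = 10000, d = 25L,
                       spacing = "geometric", radii = NULL,
                       transform = "log1p+zscore",
                       method = "clara", k = "vote", k_range = 2:6,
                       redundancy = FALSE, csr_reference = FALSE,
                       profile_radius = 4000,
                       morisita_m = 2L, id_deltas = 2^-(1:5),
                       max_index_n = 5000L,
                       seed = 1L, out_dir = NULL) {
  structure(list(points = points, domain = domain,
                 r_min = r_min, r_max = r_max, d = as.integer(d),
                 spacing = spacing, radii = radii, transform = transform,
                 method = method, k = k, k_range = as.integer(k_range),
                 redundancy = isTRUE(redundancy),
                 csr_reference = isTRUE(csr_reference),
                 profile_radius = profile_radius,
                 morisita_m = as.integer(morisita_m), id_deltas = id_deltas,
                 max_index_n = as.integer(max_index_n),
                 seed = as.integer(seed),
                 out_dir = out_dir %||% tempfile("fractalpp-run-")),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; unknown keys
#' raise an error rather than being silently ignored.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(y$id_deltas)) y$id_deltas <- as.numeric(y$id_deltas)
  do.call(run_config, y)
}

config_echo <- function(config) {
  e <- unclass(config)
  e$points <- if (is.character(e$points)) e$points else "<in-memory pattern>"
  e$domain <- if (is.null(e$domain)) NULL
  else if (is.character(e$domain)) e$domain else "<in-memory domain>"
  e
}

#' Per-cluster density and fractality profiles
#'
#' Interprets a clustering through two local characteristics of its
#' members: the local fractal dimension and the local density, taken as
#' the growth-curve count at the grid radius nearest the requested
#' profiling radius. Histogram bins are Freedman–Diaconis on the pooled
#' values and shared across clusters so the per-cluster distributions are
#' directly comparable.
#'
#' @param assignment a `cluster_assignment`
#' @param lgc the [build_lgc()] matrix of the same points
#' @param fdim the [local_fdim()] field of the same points
#' @param R_profile profiling radius (default 4000 length units); values
#'   outside the grid range snap to the nearest endpoint with a warning
#' @return object of class `cluster_profile`: `R_profile` (the snapped
#'   radius), `density` and `fdim` histogram lists (shared `breaks`,
#'   per-cluster `counts`), `summary` data frame (cluster, size, density
#'   mean/sd, fdim mean/sd, n_fdim_valid), `n_invalid_fdim`
#' @export
profile_clusters <- function(assignment, lgc, fdim, R_profile = 4000) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(lgc, "growth_curve_matrix"),
            inherits(fdim, "local_dimension_field"))
  n <- nrow(lgc$counts)
  if (length(assignment$labels) != n || length(fdim$fdim) != n)
    stopf("assignment, growth curves and fDim field must cover the same points")
  radii <- lgc$radii$radii
  if (R_profile < min(radii) || R_profile > max(radii))
    warnf("profiling radius %g outside the grid range [%g, %g]; snapping to the nearest endpoint",
          R_profile, min(radii), max(radii))
  j <- which.min(abs(radii - R_profile))
  density <- lgc$counts[, j]
  labels <- assignment$labels; k <- assignment$k

  shared_hist <- function(x, subset_list) {
    breaks <- fd_breaks(x)
    list(breaks = breaks,
         counts = lapply(subset_list, function(s)
           if (length(x[s])) hist(x[s], breaks = breaks, plot = FALSE)$counts
           else rep(0L, length(breaks) - 1L)))
  }
  subsets <- lapply(seq_len(k), function(c) labels == c)
  dens_h <- shared_hist(density, subsets)
  vmask <- fdim$valid
  fdim_h <- shared_hist(fdim$fdim[vmask],
                        lapply(subsets, function(s) s[vmask]))
  summary <- do.call(rbind, lapply(seq_len(k), function(c) {
    s <- subsets[[c]]
    fv <- fdim$fdim[s & vmask]
    data.frame(cluster = c, size = sum(s),
               density_mean = mean(density[s]), density_sd = sd(density[s]),
               fdim_mean = if (length(fv)) mean(fv) else NA_real_,
               fdim_sd = if (length(fv) > 1) sd(fv) else NA_real_,
               n_fdim_valid = length(fv))
  }))
  structure(list(R_profile = radii[j], radius_index = j,
                 density = dens_h, fdim = fdim_h, summary = summary,
                 n = n, n_invalid_fdim = sum(!vmask)),
            class = "cluster_profile")
}

fd_breaks <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(0, 1))
  if (diff(range(x)) == 0) return(c(x[1] - 0.5, x[1] + 0.5))
  nb <- max(1L, grDevices::nclass.FD(x))
  seq(min(x), max(x), length.out = nb + 1L)
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("cluster_profile at R = %g (%d invalid fDim excluded from fDim histograms)\n",
              x$R_profile, x$n_invalid_fdim))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare clustering on all features vs the non-redundant subset
#'
#' Clusters once in the full feature space and once in the subset kept by
#' Morisita-based redundancy reduction, and reports how much the two
#' partitions agree (adjusted Rand index) plus the per-cluster size
#' shifts under best-match relabeling.
#'
#' @param features a [preprocess()] result or numeric matrix
#' @param k number of clusters
#' @param ranking optional precomputed [rank_redundancy()] result;
#'   computed here otherwise
#' @param method clustering method (`"clara"` default, or `"kmeans"`,
#'   `"pam"`)
#' @param seed integer seed (same seed used for both runs)
#' @param ... passed to [rank_redundancy()] when `ranking` is NULL
#' @return object of class `reduction_comparison`: `ari`,
#'   `selected` features, `full`/`reduced` assignments, `size_shift`
#'   table; or NULL (with a warning) when fewer than 2 features survive
#' @export
compare_full_vs_reduced <- function(features, k, ranking = NULL,
                                    method = c("clara", "kmeans", "pam"),
                                    seed = NULL, ...) {
  method <- match.arg(method)
  v <- as_feature_values(features)
  if (is.null(ranking)) ranking <- rank_redundancy(v, ...)
  sel <- ranking$selected_idx
  if (length(sel) < 2) {
    warnf("redundancy reduction kept %d feature(s); comparison skipped", length(sel))
    return(NULL)
  }
  run <- function(data) switch(method,
    clara = cluster_clara(data, k, seed = seed),
    kmeans = cluster_kmeans(data, k, seed = seed),
    pam = cluster_pam(data, k, seed = seed))
  full <- run(v)
  reduced <- run(v[, sel, drop = FALSE])
  ari <- mclust::adjustedRandIndex(full$labels, reduced$labels)
  conf <- table(full = full$labels, reduced = reduced$labels)
  match_red <- apply(conf, 1, which.max)
  size_shift <- data.frame(
    cluster = seq_len(k),
    size_full = as.integer(tabulate(full$labels, k)),
    size_reduced_matched = as.integer(tabulate(reduced$labels, k)[match_red]))
  structure(list(ari = ari, selected = ranking$selected, ranking = ranking,
                 full = full, reduced = reduced, size_shift = size_shift),
            class = "reduction_comparison")
}

#' @export
print.reduction_comparison <- function(x, ...) {
  cat(sprintf("full (%d features) vs reduced (%s): ARI = %.3f\n",
              ncol(x$full$centers_or_medoids),
              paste(x$selected, collapse = ", "), x$ari))
  invisible(x)
}

stage_log <- function(report, stage, t0, ...) {
  info <- list(...)
  elapsed <- round(as.numeric(proc.time()[3] - t0), 3)
  message(sprintf("[%s] %s (%.2fs)", stage,
                  paste(names(info), vapply(info, function(v)
                    paste(format(v, digits = 6), collapse = ","), character(1)),
                    sep = "=", collapse = " "), elapsed))
  report$stages[[stage]] <- c(info, list(elapsed_s = elapsed))
  report
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load (or accept) the pattern and domain; optional
#' CSR reference generation; growth-curve embedding; global fractal
#' dimensions (box + sandbox); local fractal dimensions; Morisita
#' intrinsic dimension and optional redundancy reduction; clusterability
#' (Hopkins); cluster-number voting (unless k is fixed); clustering;
#' per-cluster profiling. Every stage logs its parameters, writes its CSV
#' artifact under `config$out_dir`, and the echoed config plus all
#' scalar results land in `report.yaml`.
#'
#' @param config a [run_config()]
#' @return object of class `pipeline_result` (invisibly also written to
#'   disk): the report list plus the in-memory stage objects
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config_echo(config), stages = list())
  t0 <- proc.time()[3]

  # -- load ----------------------------------------------------------------
  domain <- config$domain
  if (is.character(domain)) domain <- read_domain(domain)
  pattern <- config$points
  if (is.character(pattern)) pattern <- read_points(pattern, domain = domain)
  stopifnot(inherits(pattern, "point_pattern"))
  if (is.null(domain)) domain <- pattern$domain
  report <- stage_log(report, "load", t0, n = pattern$n,
                      has_domain = !is.null(domain))

  # -- CSR reference --------------------------------------------------------
  reference <- NULL
  if (config$csr_reference) {
    if (is.null(domain)) stopf("stage csr_reference failed: no validity domain supplied")
    reference <- generate_csr(domain, pattern$n, seed = config$seed + 1L)
    write_points(reference, file.path(config$out_dir, "csr_reference.csv"))
    report <- stage_log(report, "csr_reference", t0, n = reference$n)
  }

  # -- growth curves --------------------------------------------------------
  radii <- if (is.null(config$radii))
    make_radius_grid(config$r_min, config$r_max, config$d, config$spacing)
  else as_radius_grid(config$radii)
  lgc <- run_stage("lgc", build_lgc(pattern, radii))
  utils::write.csv(data.frame(point_id = lgc$point_ids, lgc$counts),
                   file.path(config$out_dir, "lgc.csv"), row.names = FALSE)
  report <- stage_log(report, "lgc", t0, d = radii$d,
                      r_min = min(radii$radii), r_max = max(radii$radii))

  # -- global fractal dimensions -------------------------------------------
  bc <- run_stage("fractal", box_count(pattern))
  sb <- run_stage("fractal", sandbox_from_lgc(lgc))
  utils::write.csv(curve_table(bc), file.path(config$out_dir, "box_count.csv"),
                   row.names = FALSE)
  utils::write.csv(curve_table(sb), file.path(config$out_dir, "sandbox.csv"),
                   row.names = FALSE)
  report <- stage_log(report, "fractal", t0, fb = bc$fb, fsb = sb$fsb)

  # -- local fractal dimension ---------------------------------------------
  fdim <- run_stage("local_fdim", local_fdim(lgc))
  utils::write.csv(data.frame(point_id = lgc$point_ids, fdim = fdim$fdim,
                              valid = fdim$valid),
                   file.path(config$out_dir, "local_fdim.csv"), row.names = FALSE)
  fv <- fdim$fdim[fdim$valid]
  report <- stage_log(report, "local_fdim", t0, mean = mean(fv), sd = sd(fv),
                      invalid = sum(!fdim$valid))

  # -- features, Morisita ID, redundancy ------------------------------------
  features <- run_stage("preprocess", preprocess(lgc, config$transform))
  pca <- if (ncol(features$values) >= 2 && nrow(features$values) > ncol(features$values))
    pca_summary(features) else NULL
  id_est <- run_stage("morisita_id",
                      estimate_id(features$values, m = config$morisita_m,
                                  deltas = config$id_deltas))
  report <- stage_log(report, "morisita_id", t0, id = id_est$id_value,
                      E = id_est$E,
                      pca_first = if (is.null(pca)) NA else pca$explained_fraction[1])
  ranking <- NULL
  if (config$redundancy) {
    ranking <- run_stage("redundancy",
                         rank_redundancy(features, m = config$morisita_m,
                                         deltas = config$id_deltas))
    report <- stage_log(report, "redundancy", t0,
                        selected = paste(ranking$selected, collapse = "+"),
                        id_full = id_est$id_value)
  }

  # -- clusterability -------------------------------------------------------
  hop <- run_stage("clusterability",
                   hopkins_stat(features,
                                sample = min(100L, nrow(features$values) %/% 2),
                                seed = config$seed + 2L))
  report <- stage_log(report, "clusterability", t0, hopkins = hop$hopkins,
                      verdict = hop$verdict)

  # -- number of clusters ---------------------------------------------------
  vote <- NULL
  k <- config$k
  if (identical(k, "vote")) {
    vote_method <- if (config$method %in% c("kmeans", "pam", "clara"))
      config$method else "kmeans"
    vote <- run_stage("vote_k",
                      vote_k(features, k_range = config$k_range,
                             method = vote_method, seed = config$seed + 3L))
    k <- vote$majority_k
    report <- stage_log(report, "vote_k", t0, majority_k = k,
                        votes = paste(names(vote$index_votes), vote$index_votes,
                                      sep = ":", collapse = " "))
  }
  k <- as.integer(k)

  # -- clustering -----------------------------------------------------------
  assignment <- run_stage("cluster", switch(config$method,
    kmeans = cluster_kmeans(features, k, seed = config$seed + 4L),
    pam = cluster_pam(features, k, seed = config$seed + 4L),
    clara = cluster_clara(features, k, seed = config$seed + 4L),
    hierarchical = {
      n <- nrow(features$values)
      if (n > config$max_index_n)
        stopf("hierarchical method needs n <= max_index_n (%d); got %d",
              config$max_index_n, n)
      cut_dendrogram(cluster_hierarchical(features), k, features)
    },
    som = {
      mdl <- som_train(features, epochs = 50L, seed = config$seed + 4L)
      som_cluster(mdl, features, k, seed = config$seed + 5L)
    },
    stopf("unknown clustering method '%s'", config$method)))
  utils::write.csv(data.frame(point_id = lgc$point_ids,
                              x = pattern$coords[, 1], y = pattern$coords[, 2],
                              label = assignment$labels),
                   file.path(config$out_dir, "assignment.csv"), row.names = FALSE)
  report <- stage_log(report, "cluster", t0, method = config$method, k = k,
                      sizes = paste(tabulate(assignment$labels, k), collapse = "/"))

  # -- full vs reduced ------------------------------------------------------
  comparison <- NULL
  if (config$redundancy && !is.null(ranking)) {
    cmp_method <- if (config$method %in% c("clara", "kmeans", "pam"))
      config$method else "clara"
    comparison <- compare_full_vs_reduced(features, k, ranking = ranking,
                                          method = cmp_method,
                                          seed = config$seed + 6L)
    if (!is.null(comparison))
      report <- stage_log(report, "compare_reduced", t0, ari = comparison$ari,
                          selected = paste(comparison$selected, collapse = "+"))
  }

  # -- profiling ------------------------------------------------------------
  profile <- run_stage("profile",
                       profile_clusters(assignment, lgc, fdim,
                                        R_profile = config$profile_radius))
  utils::write.csv(profile$summary, file.path(config$out_dir, "profile_summary.csv"),
                   row.names = FALSE)
  report <- stage_log(report, "profile", t0, R_profile = profile$R_profile)

  report$results <- list(
    n = pattern$n, fb = bc$fb, fsb = sb$fsb,
    local_fdim_mean = mean(fv), local_fdim_sd = sd(fv),
    morisita_id = id_est$id_value, hopkins = hop$hopkins,
    k = k, method = config$method,
    cluster_sizes = as.integer(tabulate(assignment$labels, k)),
    selected_features = if (is.null(ranking)) NULL else ranking$selected,
    reduction_ari = if (is.null(comparison)) NULL else comparison$ari)
  yaml::write_yaml(rapply(report, function(x)
    if (is.numeric(x)) unname(x) else x, how = "replace"),
    file.path(config$out_dir, "report.yaml"))

  structure(list(report = report, pattern = pattern, reference = reference,
                 lgc = lgc, box = bc, sandbox = sb, fdim = fdim,
                 features = features, pca = pca, id = id_est,
                 ranking = ranking, hopkins = hop, vote = vote,
                 assignment = assignment, comparison = comparison,
                 profile = profile, out_dir = config$out_dir),
            class = "pipeline_result")
}

# abort with the failing stage's name while keeping partial artifacts
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s failed: %s", stage, conditionMessage(e)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report$results
  cat("pipeline_result\n")
  cat(sprintf("  n = %d, fb = %.3f, fsb = %.3f, local fDim %.3f +- %.3f\n",
              r$n, r$fb, r$fsb, r$local_fdim_mean, r$local_fdim_sd))
  cat(sprintf("  Morisita ID = %.3f, Hopkins = %.3f, %s with k = %d (sizes %s)\n",
              r$morisita_id, r$hopkins, r$method, r$k,
              paste(r$cluster_sizes, collapse = "/")))
  cat(sprintf("  artifacts: %s\n", x$out_dir))
  invisible(x)
}
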