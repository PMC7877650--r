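#' Simulate complete spatial randomness (CSR) inside a validity domain
#'
#' Draws exactly `n` i.i.d. uniform points over the domain (outer rings
#' minus holes) by rejection sampling from the bounding box. This is the
#' homogeneous reference pattern against which an observed pattern's
#' clustering and fractality are judged; generated with the same `n` as the
#' data inside the same domain it plays the role of the domain-conditioned
#' CSR reference.
#'
#' @param domain a [validity_domain()]
#' @param n number of points (>= 1)
#' @param seed integer seed; a fixed seed reproduces the coordinates exactly
#' @return a [point_pattern()] carrying the domain
#' @export
generate_csr <- function(domain, n, seed = NULL) {
  stopifnot(inherits(domain, "validity_domain"))
  if (n < 1) stopf("n must be >= 1")
  bb <- domain$bbox
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"])
    stopf("degenerate bounding box")
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 2)
    # acceptance rate = domain area / bbox area; draw in batches
    rate <- max(domain$area / ((bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])), 1e-3)
    while (nrow(out) < n) {
      m <- ceiling((n - nrow(out)) / rate * 1.1) + 16
      cand <- cbind(runif(m, bb["xmin"], bb["xmax"]),
                    runif(m, bb["ymin"], bb["ymax"]))
      keep <- domain_contains(domain, cand)
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    point_pattern(out[seq_len(n), , drop = FALSE], domain = domain)
  })
}

#' Specification of a synthetic point-pattern fixture
#'
#' @param kind one of `"csr"`, `"blobs"`, `"thomas"`, `"sierpinski"`,
#'   `"line"`, `"grid"`
#' @param n point count
#' @param params kind-specific parameter list, see [generate_fixture()]
#' @param seed integer seed (fixed seed gives bit-reproducible output)
#' @export
synthetic_spec <- function(kind, n, params = list(), seed = 1L) {
  kinds <- c("csr", "blobs", "thomas", "sierpinski", "line", "grid")
  if (!kind %in% kinds)
    stopf("unknown fixture kind '%s' (expected one of %s)", kind,
          paste(kinds, collapse = ", "))
  if (n < 1) stopf("n must be >= 1")
  structure(list(kind = kind, n = as.integer(n), params = params,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

unit_square_domain <- function() {
  validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
}

#' Generate a synthetic point pattern with known ground truth
#'
#' Fixture generators for estimator validation:
#' * `csr` — uniform in a domain (`params$domain`, default unit square);
#' * `blobs` — `params$k` isotropic Gaussian clusters (default 3) with
#'   per-point ground-truth labels in `attr(, "labels")`; cluster centers
#'   default to points evenly spaced on a circle of radius 0.3 around
#'   (0.5, 0.5), sd `params$sd` (default 0.03; a length-k vector gives
#'   each cluster its own spread, i.e. its own density); points split as
#'   evenly as possible across clusters;
#' * `thomas` — Thomas-style cluster process: `params$parents` (default 25)
#'   uniform parent locations, each point attached to a random parent plus
#'   an isotropic Gaussian offset of sd `params$sd` (default 0.02);
#' * `sierpinski` — chaos-game sample of the Sierpinski triangle (fractal
#'   dimension log 3 / log 2 ~ 1.585);
#' * `line` — evenly spaced points on a segment (dimension 1), default from
#'   (0,0) to (1,0);
#' * `grid` — regular square lattice filling the unit square (dimension 2
#'   at scales above the spacing).
#'
#' @param spec a [synthetic_spec()]
#' @return a [point_pattern()]; `blobs` additionally carries integer
#'   ground-truth labels as `attr(pattern, "labels")`
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n; p <- spec$params
  switch(spec$kind,
    csr = {
      dom <- p$domain %||% unit_square_domain()
      generate_csr(dom, n, spec$seed)
    },
    blobs = with_seed(spec$seed, {
      k <- p$k %||% 3L
      sdv <- rep_len(p$sd %||% 0.03, k)   # scalar or per-cluster spread
      centers <- p$centers %||% {
        ang <- 2 * pi * (seq_len(k) - 1) / k
        cbind(0.5 + 0.3 * cos(ang), 0.5 + 0.3 * sin(ang))
      }
      sizes <- rep(n %/% k, k)
      if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
      labels <- rep.int(seq_len(k), sizes)
      xy <- cbind(centers[labels, 1] + rnorm(n, 0, sdv[labels]),
                  centers[labels, 2] + rnorm(n, 0, sdv[labels]))
      pat <- point_pattern(xy)
      attr(pat, "labels") <- labels
      pat
    }),
    thomas = with_seed(spec$seed, {
      np <- p$parents %||% 25L
      sdv <- p$sd %||% 0.02
      parents <- cbind(runif(np), runif(np))
      who <- sample.int(np, n, replace = TRUE)
      xy <- cbind(parents[who, 1] + rnorm(n, 0, sdv),
                  parents[who, 2] + rnorm(n, 0, sdv))
      pat <- point_pattern(xy)
      attr(pat, "parent") <- who
      pat
    }),
    sierpinski = with_seed(spec$seed, {
      v <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
      pick <- sample.int(3L, n + 20L, replace = TRUE)
      xy <- matrix(0, n + 20L, 2)
      pt <- c(runif(1), runif(1) * sqrt(3) / 2)
      for (i in seq_len(n + 20L)) {
        pt <- (pt + v[pick[i], ]) / 2
        xy[i, ] <- pt
      }
      point_pattern(xy[-seq_len(20L), , drop = FALSE])  # drop burn-in
    }),
    line = {
      from <- p$from %||% c(0, 0)
      to <- p$to %||% c(1, 0)
      tt <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
      point_pattern(cbind(from[1] + tt * (to[1] - from[1]),
                          from[2] + tt * (to[2] - from[2])))
    },
    grid = {
      m <- ceiling(sqrt(n))
      g <- seq(0, 1, length.out = m)
      xy <- as.matrix(expand.grid(x = g, y = g))
      point_pattern(xy[seq_len(n), , drop = FALSE])
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
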