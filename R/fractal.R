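#' Radius grid for growth-curve and sandbox analysis
#'
#' Builds the increasing set of radii \eqn{R_1 < \dots < R_d} at which
#' per-point neighbor counts are taken. Geometric spacing is the default:
#' fractal scaling is a power law, so equal spacing on the log axis gives
#' each scale equal leverage in the log-log fit.
#'
#' @param r_min,r_max radius range (length units), both included
#' @param d number of radii (>= 2)
#' @param spacing `"geometric"` (default) or `"linear"`
#' @return object of class `radius_grid`: list with `radii` (length d) and `d`
#' @examples
#' make_radius_grid(300, 10000, 25)   # the 25 radii from 300 m to 10 km
#' @export
make_radius_grid <- function(r_min, r_max, d, spacing = c("geometric", "linear")) {
  spacing <- match.arg(spacing)
  if (!(r_min > 0 && r_max > r_min)) stopf("need 0 < r_min < r_max")
  if (d < 2) stopf("need d >= 2 radii")
  radii <- if (spacing == "geometric")
    exp(seq(log(r_min), log(r_max), length.out = d))
  else seq(r_min, r_max, length.out = d)
  structure(list(radii = radii, d = as.integer(d), spacing = spacing),
            class = "radius_grid")
}

as_radius_grid <- function(radii) {
  if (inherits(radii, "radius_grid")) return(radii)
  radii <- as.numeric(radii)
  if (length(radii) < 2 || any(radii <= 0) || any(diff(radii) <= 0))
    stopf("radii must be >= 2 strictly increasing positive values")
  structure(list(radii = radii, d = length(radii), spacing = "custom"),
            class = "radius_grid")
}

#' Ordinary least-squares fit on log-log axes
#'
#' Fits `log(value) ~ log(scale)` by OLS over the pairs with positive
#' value; pairs with value 0 are dropped via the returned `used_mask`,
#' never offset. Exact on perfect power laws.
#'
#' @param scales positive scales (radii or cell edges)
#' @param values non-negative values (counts or means)
#' @param extra_mask optional logical mask of pairs admissible for the fit
#'   (combined with `value > 0`)
#' @return object of class `loglog_fit`: `slope`, `intercept` (natural-log
#'   axes), `r_squared` (NA when fewer than 3 points used), `used_mask`
#' @export
fit_loglog <- function(scales, values, extra_mask = NULL) {
  scales <- as.numeric(scales); values <- as.numeric(values)
  if (length(scales) != length(values)) stopf("scales and values differ in length")
  used <- is.finite(scales) & is.finite(values) & scales > 0 & values > 0
  if (!is.null(extra_mask)) used <- used & extra_mask
  if (sum(used) < 2) stopf("need at least 2 pairs with positive value for a log-log fit")
  lx <- log(scales[used]); ly <- log(values[used])
  fit <- lm(ly ~ lx)
  r2 <- if (sum(used) >= 3) {
    tss <- sum((ly - mean(ly))^2)
    if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  } else NA_real_
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = r2, used_mask = used),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("log-log OLS: slope %.4f, intercept %.4f, R^2 %s, %d/%d scales used\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              sum(x$used_mask), length(x$used_mask)))
  invisible(x)
}

#' Box-counting fractal dimension
#'
#' Covers the pattern's bounding box with regular grids of decreasing cell
#' edge l (anchored at the bbox minimum corner) and counts the occupied
#' cells N(l). The scaling \eqn{N(l) \sim l^{-f_b}} defines the
#' box-counting dimension; \eqn{f_b} is minus the OLS slope of
#' \eqn{\log N} vs \eqn{\log l}. The fit is restricted to scales with
#' `1 < N(l) < n` to avoid the single-cell and one-point-per-cell
#' saturation plateaus.
#'
#' @param pattern a [point_pattern()]
#' @param scales cell edge lengths; default: 12 dyadic subdivisions of the
#'   longer bounding-box side (L/2, L/4, ..., L/2^12)
#' @return object of class `boxcount_curve`: `scales`, `counts`, `fit`
#'   (a [fit_loglog()] result) and `fb` (the dimension estimate)
#' @export
box_count <- function(pattern, scales = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  xy <- pattern$coords
  if (nrow(xy) < 1) stopf("empty pattern")
  xmin <- min(xy[, 1]); ymin <- min(xy[, 2])
  span <- max(max(xy[, 1]) - xmin, max(xy[, 2]) - ymin)
  if (span == 0) span <- 1   # all points coincide; any grid sees one cell
  if (is.null(scales)) scales <- span / 2^(1:12)
  scales <- sort(as.numeric(scales), decreasing = TRUE)
  if (any(scales <= 0)) stopf("scales must be positive")
  spanx <- max(xy[, 1]) - xmin; spany <- max(xy[, 2]) - ymin
  counts <- vapply(scales, function(l) {
    # half-open cells; points exactly on the top/right bbox edge clamp
    # into the last cell instead of opening a spurious extra row
    ix <- pmin(floor((xy[, 1] - xmin) / l), max(ceiling(spanx / l) - 1, 0))
    iy <- pmin(floor((xy[, 2] - ymin) / l), max(ceiling(spany / l) - 1, 0))
    length(unique(ix * 2^26 + iy))
  }, numeric(1))
  n <- nrow(xy)
  if (all(counts == counts[1])) {
    # degenerate (e.g. a single point): the count never scales
    fit <- structure(list(slope = 0, intercept = log(counts[1]),
                          r_squared = NA_real_,
                          used_mask = rep(TRUE, length(scales))),
                     class = "loglog_fit")
    return(structure(list(scales = scales, counts = as.integer(counts),
                          fit = fit, fb = 0, n = n),
                     class = "boxcount_curve"))
  }
  # restrict the fit to the scaling region: above the single-cell plateau
  # and well below the one-point-per-cell saturation at N ~ n (counts
  # flatten toward n long before reaching it, so n/10 is the cutoff);
  # relax to N < n when the strict window leaves fewer than 2 scales
  strict <- counts > 1 & counts < n / 10
  mask <- if (sum(strict & counts > 0) >= 2) strict else counts > 1 & counts < n
  fit <- fit_loglog(scales, counts, extra_mask = mask)
  structure(list(scales = scales, counts = as.integer(counts), fit = fit,
                 fb = -fit$slope, n = n),
            class = "boxcount_curve")
}

#' Sandbox-counting fractal dimension
#'
#' For every point, counts how many *other* points fall within the closed
#' ball of each radius \eqn{R_i} (the local growth curve), then averages
#' the counts over all points. The scaling
#' \eqn{\langle N(R) \rangle \sim R^{f_{sb}}} defines the sandbox
#' dimension: the OLS slope of \eqn{\log \langle N \rangle} vs
#' \eqn{\log R} over radii with positive mean count. A homogeneous planar
#' pattern far from boundaries gives \eqn{f_{sb} = 2}.
#'
#' @param pattern a [point_pattern()] with n >= 2
#' @param radii a [make_radius_grid()] or increasing numeric vector
#' @return object of class `sandbox_curve`: `radii`, `mean_counts`, `fit`,
#'   `fsb` (the dimension estimate)
#' @export
sandbox_count <- function(pattern, radii) {
  lgc <- build_lgc(pattern, radii)
  sandbox_from_lgc(lgc)
}

sandbox_from_lgc <- function(lgc) {
  mean_counts <- colMeans(lgc$counts)
  if (sum(mean_counts > 0) >= 2) {
    fit <- fit_loglog(lgc$radii$radii, mean_counts)
    fsb <- fit$slope
  } else {
    warnf("fewer than 2 radii with a positive mean count; sandbox dimension undefined")
    fit <- NULL
    fsb <- NA_real_
  }
  structure(list(radii = lgc$radii, mean_counts = mean_counts, fit = fit,
                 fsb = fsb, n = nrow(lgc$counts)),
            class = "sandbox_curve")
}

#' @export
print.boxcount_curve <- function(x, ...) {
  cat(sprintf("box counting over %d scales: fb = %.3f (R^2 %.4f)\n",
              length(x$scales), x$fb, x$fit$r_squared))
  invisible(x)
}

#' @export
print.sandbox_curve <- function(x, ...) {
  cat(sprintf("sandbox counting over %d radii: fsb = %.3f (R^2 %.4f)\n",
              x$radii$d, x$fsb, x$fit$r_squared))
  invisible(x)
}

#' Export a fitted scaling curve as a data frame
#'
#' @param x a `boxcount_curve` or `sandbox_curve`
#' @return data frame with columns `scale`, `value`, `used`
#' @export
curve_table <- function(x) {
  if (inherits(x, "boxcount_curve"))
    data.frame(scale = x$scales, value = x$counts, used = x$fit$used_mask)
  else if (inherits(x, "sandbox_curve"))
    data.frame(scale = x$radii$radii, value = x$mean_counts,
               used = x$fit$used_mask %||% rep(FALSE, x$radii$d))
  else stopf("not a scaling curve")
}
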