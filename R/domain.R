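#' Validity domain: polygon(s) with holes
#'
#' A validity domain is the region where the studied phenomenon can exist
#' (e.g. a national border minus its lakes). It conditions CSR simulation
#' and any comparison between an observed pattern and its homogeneous
#' reference. Geometrically it is one or more simple outer rings minus a set
#' of hole rings; points on any ring boundary count as inside (closed-set
#' convention, so gridded cell centers lying exactly on a border are kept).
#'
#' @param outer a two-column matrix of ring vertices (meters), or a list of
#'   such matrices for a multi-part domain. Rings need not repeat the first
#'   vertex; they are closed implicitly.
#' @param holes list of two-column matrices, each a hole (exclusion) lying
#'   inside some outer ring.
#' @return an object of class `validity_domain` with elements `outer`,
#'   `holes` and `bbox` (xmin, ymin, xmax, ymax).
#' @examples
#' sq <- validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' domain_contains(sq, cbind(0.5, 0.5))
#' @export
validity_domain <- function(outer, holes = list()) {
  if (is.matrix(outer) || is.data.frame(outer)) outer <- list(as.matrix(outer))
  outer <- lapply(outer, check_ring)
  holes <- lapply(holes, check_ring)
  for (h in holes) {
    centers <- h[1, , drop = FALSE]
    if (!any(vapply(outer, function(r) in_ring(centers[1], centers[2], r) != 0L, logical(1))))
      stopf("hole ring does not lie inside any outer ring")
  }
  all_xy <- do.call(rbind, c(outer, holes))
  bbox <- c(xmin = min(all_xy[, 1]), ymin = min(all_xy[, 2]),
            xmax = max(all_xy[, 1]), ymax = max(all_xy[, 2]))
  area <- sum(vapply(outer, ring_area, numeric(1))) -
    sum(vapply(holes, ring_area, numeric(1)))
  if (area <= 0) stopf("domain area must be positive (got %g)", area)
  structure(list(outer = outer, holes = holes, bbox = bbox, area = area),
            class = "validity_domain")
}

check_ring <- function(r) {
  r <- as.matrix(r)
  if (ncol(r) != 2L) stopf("a ring must be a two-column matrix of vertices")
  if (!all(is.finite(r))) stopf("ring vertices must be finite")
  # drop an explicit closing vertex
  if (nrow(r) > 1L && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
  if (nrow(r) < 3L) stopf("a ring needs at least 3 distinct vertices")
  if (ring_area(r) <= 0) stopf("ring has zero area")
  r
}

ring_area <- function(r) {
  n <- nrow(r)
  j <- c(2:n, 1)
  abs(sum(r[, 1] * r[j, 2] - r[j, 1] * r[, 2])) / 2
}

# Even-odd ray casting with an explicit boundary test, vectorized over
# points. Returns per point: 1 (interior), 2 (on boundary), 0 (outside).
in_ring <- function(px, py, ring) {
  m <- nrow(ring)
  eps <- 1e-9 * max(1, max(abs(ring)))
  onseg <- logical(length(px))
  crossings <- integer(length(px))
  for (j in seq_len(m)) {
    x1 <- ring[if (j == 1) m else j - 1, 1]; y1 <- ring[if (j == 1) m else j - 1, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seglen <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    onseg <- onseg | (abs(cross) <= eps * max(seglen, 1) &
                        px >= min(x1, x2) - eps & px <= max(x1, x2) + eps &
                        py >= min(y1, y2) - eps & py <= max(y1, y2) + eps)
    hits <- ((y1 > py) != (y2 > py))
    if (any(hits))
      crossings[hits] <- crossings[hits] +
        (px[hits] < (x1 - x2) * (py[hits] - y2) / (y1 - y2) + x2)
  }
  out <- ifelse(crossings %% 2L == 1L, 1L, 0L)
  out[onseg] <- 2L
  out
}

#' Point-in-domain test
#'
#' A point is inside the domain iff it lies inside (or on the boundary of)
#' an outer ring and not strictly inside a hole. Boundary points of both
#' outer rings and holes count as inside.
#'
#' @param domain a [validity_domain()]
#' @param points a two-column matrix (or length-2 vector) of coordinates
#' @return logical vector, one entry per point
#' @export
domain_contains <- function(domain, points) {
  stopifnot(inherits(domain, "validity_domain"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (!all(is.finite(points))) stopf("non-finite coordinates in point-in-domain test")
  px <- points[, 1]; py <- points[, 2]
  st <- integer(length(px))
  for (r in domain$outer) {
    todo <- st == 0L
    if (!any(todo)) break
    st[todo] <- in_ring(px[todo], py[todo], r)
  }
  inside <- st != 0L
  candidates <- st == 1L               # interior: may still fall in a hole
  for (h in domain$holes) {
    if (!any(candidates)) break
    hs <- in_ring(px[candidates], py[candidates], h)
    inside[candidates][hs == 1L] <- FALSE   # strictly inside a hole
    # on a hole boundary -> stays inside (closed set); settled either way
    candidates[candidates] <- hs == 0L
  }
  inside
}

#' Total area of a validity domain
#' @param domain a [validity_domain()]
#' @return area in squared length units (outer rings minus holes)
#' @export
domain_area <- function(domain) {
  stopifnot(inherits(domain, "validity_domain"))
  domain$area
}

#' @export
print.validity_domain <- function(x, ...) {
  cat(sprintf("validity_domain: %d outer ring(s), %d hole(s), area %g\n",
              length(x$outer), length(x$holes), x$area))
  cat(sprintf("  bbox: [%g, %g] x [%g, %g]\n",
              x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

#' Planar point pattern
#'
#' @param coords two-column matrix (or data frame with columns x, y) of
#'   planar metric coordinates.
#' @param units length-unit label (default "m").
#' @param domain optional [validity_domain()]; if supplied, every point must
#'   lie inside it.
#' @return object of class `point_pattern` with elements `coords` (n x 2
#'   matrix, columns x, y), `n`, `units`, `domain`.
#' @export
point_pattern <- function(coords, units = "m", domain = NULL) {
  if (is.data.frame(coords)) {
    if (!all(c("x", "y") %in% names(coords)))
      stopf("coordinate data frame must have columns 'x' and 'y'")
    coords <- as.matrix(coords[, c("x", "y")])
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stopf("coords must have two columns")
  if (nrow(coords) < 1L) stopf("a point pattern needs at least one point")
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1, all))
    stopf("non-finite coordinates at row(s) %s", paste(head(bad, 5), collapse = ", "))
  }
  colnames(coords) <- c("x", "y")
  if (!is.null(domain)) {
    inside <- domain_contains(domain, coords)
    if (!all(inside))
      stopf("%d point(s) fall outside the validity domain (first: row %d)",
            sum(!inside), which(!inside)[1])
  }
  structure(list(coords = coords, n = nrow(coords), units = units, domain = domain),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points (%s)%s\n", x$n, x$units,
              if (is.null(x$domain)) "" else ", with validity domain"))
  invisible(x)
}

looks_geographic <- function(xy) {
  all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90)
}

#' Read a point pattern from CSV
#'
#' Expects a comma-separated file with a header containing columns `x` and
#' `y` (planar metric coordinates, decimal point, UTF-8). Columns named
#' `lon`/`lat` (or variants) are rejected: all distances here are Euclidean,
#' so geographic coordinates must be projected first.
#'
#' @param path CSV file path
#' @param units length-unit label attached to the pattern
#' @param domain optional [validity_domain()] the points must fall into
#' @return a [point_pattern()]
#' @export
read_points <- function(path, units = "m", domain = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("empty points file: %s", path)
  geo <- intersect(tolower(names(df)),
                   c("lon", "lat", "longitude", "latitude", "lng"))
  if (length(geo))
    stopf("columns %s look geographic; project to planar metric coordinates first",
          paste(geo, collapse = "/"))
  if (!all(c("x", "y") %in% names(df)))
    stopf("points CSV must have header columns 'x' and 'y' (got: %s)",
          paste(names(df), collapse = ", "))
  xy <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
  bad <- which(!apply(is.finite(xy), 1, all))
  if (length(bad))
    stopf("non-finite coordinate in row %d of %s", bad[1], path)
  point_pattern(xy, units = units, domain = domain)
}

#' Write a point pattern to CSV
#'
#' Coordinates are written with 17 significant digits so a write/read
#' round trip preserves them exactly.
#'
#' @param pattern a [point_pattern()]
#' @param path output file path
#' @export
write_points <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y", con)
  writeLines(sprintf("%.17g,%.17g", pattern$coords[, 1], pattern$coords[, 2]), con)
  invisible(path)
}

#' Read a validity domain from GeoJSON
#'
#' Accepts a Polygon or MultiPolygon geometry (RFC 7946), possibly wrapped
#' in a Feature or FeatureCollection (first polygonal feature used). The
#' first linear ring of each polygon is an outer ring; subsequent rings are
#' holes. Coordinates must be planar metric: when every coordinate fits in
#' the geographic degree box (|x| <= 180, |y| <= 90) the reader assumes
#' lon/lat and errors, telling the user to pre-project; pass
#' `assume_planar = TRUE` for legitimately small planar domains (e.g. a
#' unit-square test geometry).
#'
#' @param path GeoJSON file path
#' @param assume_planar skip the lon/lat heuristic
#' @return a [validity_domain()]
#' @export
read_domain <- function(path, assume_planar = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  g <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stopf("unparseable GeoJSON in %s: %s", path, conditionMessage(e)))
  geom <- extract_polygon_geometry(g)
  if (is.null(geom)) stopf("no Polygon/MultiPolygon geometry found in %s", path)
  polys <- if (identical(geom$type, "Polygon")) list(geom$coordinates) else geom$coordinates
  outer <- list(); holes <- list()
  for (poly in polys) {
    rings <- lapply(poly, function(ring)
      do.call(rbind, lapply(ring, function(v) as.numeric(v[1:2]))))
    outer <- c(outer, rings[1])
    if (length(rings) > 1) holes <- c(holes, rings[-1])
  }
  all_xy <- do.call(rbind, c(outer, holes))
  if (!assume_planar && looks_geographic(all_xy))
    stopf(paste0("coordinates in %s fall inside the lon/lat degree box; ",
                 "project to planar metric coordinates first ",
                 "(or set assume_planar = TRUE for a small planar domain)"), path)
  validity_domain(outer, holes)
}

extract_polygon_geometry <- function(g) {
  if (is.null(g$type)) return(NULL)
  switch(g$type,
    Polygon = g, MultiPolygon = g,
    Feature = extract_polygon_geometry(g$geometry),
    FeatureCollection = {
      for (f in g$features) {
        r <- extract_polygon_geometry(f)
        if (!is.null(r)) return(r)
      }
      NULL
    },
    GeometryCollection = {
      for (gg in g$geometries) {
        r <- extract_polygon_geometry(gg)
        if (!is.null(r)) return(r)
      }
      NULL
    },
    NULL)
}
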