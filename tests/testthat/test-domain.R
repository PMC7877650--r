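test_that("point-in-domain follows the closed-set convention", {
  sq <- unit_square()
  expect_true(domain_contains(sq, c(0.5, 0.5)))
  expect_false(domain_contains(sq, c(2, 2)))
  hole <- validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                          holes = list(cbind(c(0.4, 0.6, 0.6, 0.4),
                                             c(0.4, 0.4, 0.6, 0.6))))
  expect_false(domain_contains(hole, c(0.5, 0.5)))
  # boundary points count as inside: outer edge, outer corner, hole edge
  expect_true(domain_contains(sq, c(0, 0.5)))
  expect_true(domain_contains(sq, c(1, 1)))
  expect_true(domain_contains(hole, c(0.4, 0.5)))
  expect_error(domain_contains(sq, c(NA, 0.5)), "finite")
})

test_that("domain construction validates rings and area", {
  expect_error(validity_domain(cbind(c(0, 1), c(0, 1))), "3 distinct")
  expect_error(validity_domain(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
  expect_error(validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                               holes = list(cbind(c(5, 6, 6), c(5, 5, 6)))),
               "does not lie inside")
  hole <- square_with_hole()
  expect_equal(domain_area(hole), 1 - 0.3^2)
  expect_equal(unname(hole$bbox), c(0, 0, 1, 1))
})

test_that("CSR points are uniform over the domain and reproducible", {
  sq <- unit_square()
  p1 <- generate_csr(sq, 1000, seed = 1)
  p2 <- generate_csr(sq, 1000, seed = 1)
  expect_identical(p1$coords, p2$coords)
  expect_true(all(domain_contains(sq, p1$coords)))
  # chi-square on a 4x4 partition of the convex unit square
  big <- generate_csr(sq, 100000, seed = 17)
  cells <- floor(pmin(big$coords[, 1], 0.999) * 4) * 4 +
    floor(pmin(big$coords[, 2], 0.999) * 4)
  expect_gt(stats::chisq.test(tabulate(cells + 1, 16))$p.value, 0.01)
})

test_that("rejection sampling acceptance tracks the area ratio", {
  # hole of 20% area: fraction of bbox draws accepted ~ 0.8
  dom <- validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                         holes = list(cbind(c(0.3, 0.3 + sqrt(0.2), 0.3 + sqrt(0.2), 0.3),
                                            c(0.3, 0.3, 0.3 + sqrt(0.2), 0.3 + sqrt(0.2)))))
  expect_equal(domain_area(dom), 0.8, tolerance = 1e-12)
  set.seed(4)
  cand <- cbind(runif(50000), runif(50000))
  expect_equal(mean(domain_contains(dom, cand)), 0.8, tolerance = 0.02)
})

test_that("fixture generators are deterministic and carry ground truth", {
  for (kind in c("blobs", "thomas", "sierpinski")) {
    a <- generate_fixture(synthetic_spec(kind, 500, seed = 3))
    b <- generate_fixture(synthetic_spec(kind, 500, seed = 3))
    expect_identical(a$coords, b$coords)
  }
  bl <- generate_fixture(synthetic_spec("blobs", 3000, params = list(k = 3), seed = 1))
  expect_equal(as.integer(table(attr(bl, "labels"))), rep(1000L, 3))
  expect_error(synthetic_spec("voronoi", 10), "unknown fixture kind")
})

test_that("points CSV round-trips at full precision and rejects bad input", {
  pat <- point_pattern(matrix(c(pi, exp(1), 1 / 3, sqrt(2), 0.1, -7), ncol = 2))
  f <- tempfile(fileext = ".csv")
  write_points(pat, f)
  back <- read_points(f)
  expect_identical(back$coords, pat$coords)

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "NaN,3", "4,5"), f2)
  expect_error(read_points(f2), "row 2")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), f3)
  expect_error(read_points(f3), "columns 'x' and 'y'")
  f4 <- tempfile(fileext = ".csv")
  writeLines(c("lon,lat", "7.5,46.9"), f4)
  expect_error(read_points(f4), "geographic")
  f5 <- tempfile(fileext = ".csv")
  writeLines("x,y", f5)
  expect_error(read_points(f5), "empty")
})

test_that("GeoJSON domains parse polygons with holes and flag lon/lat", {
  gj <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Polygon",
    coordinates = list(
      list(list(0, 0), list(10000, 0), list(10000, 10000), list(0, 10000), list(0, 0)),
      list(list(4000, 4000), list(6000, 4000), list(6000, 6000), list(4000, 6000), list(4000, 4000))
    )), auto_unbox = TRUE), gj)
  dom <- read_domain(gj)
  expect_length(dom$holes, 1)
  expect_equal(domain_area(dom), 1e8 - 4e6)

  # unit-scale coordinates look like degrees: rejected unless declared planar
  gj2 <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature", properties = NULL,
    geometry = list(type = "Polygon",
                    coordinates = list(list(list(0, 0), list(1, 0), list(1, 1),
                                            list(0, 1), list(0, 0))))),
    auto_unbox = TRUE), gj2)
  expect_error(read_domain(gj2), "planar")
  dom2 <- read_domain(gj2, assume_planar = TRUE)
  expect_equal(domain_area(dom2), 1)

  bad <- tempfile()
  writeLines("{not json", bad)
  expect_error(read_domain(bad), "unparseable")
  pt <- tempfile()
  writeLines('{"type": "Point", "coordinates": [1, 2]}', pt)
  expect_error(read_domain(pt), "no Polygon")
})
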