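test_that("the index reproduces hand evaluations of the defining formula", {
  # 4 points in one cell of a 2x2 grid: I = 4 * (4*3) / (4*3) = 4
  d4 <- matrix(c(0.1, 0.1, 0.2, 0.2, 0.15, 0.12, 0.05, 0.22), ncol = 2, byrow = TRUE)
  expect_equal(morisita_index(d4, m = 2, deltas = 0.5, rescale = FALSE)$values, 4)
  # one point per cell: every n_i = 1, numerator vanishes
  d1 <- matrix(c(0.2, 0.2, 0.7, 0.2, 0.2, 0.7, 0.7, 0.7), ncol = 2, byrow = TRUE)
  expect_equal(morisita_index(d1, m = 2, deltas = 0.5, rescale = FALSE)$values, 0)
  # a single cell normalizes to exactly 1
  expect_equal(morisita_index(d4, m = 2, deltas = 1, rescale = FALSE)$values, 1)
  # m = 3 hand value: one cell with 3 points, one with 1 (2x2 grid, N = 4):
  # I = Q^2 * 3*2*1 / (4*3*2) = 16 * 6/24 = 4
  d3 <- matrix(c(0.1, 0.1, 0.2, 0.2, 0.15, 0.12, 0.7, 0.7), ncol = 2, byrow = TRUE)
  expect_equal(morisita_index(d3, m = 3, deltas = 0.5, rescale = FALSE)$values, 4)
  expect_error(morisita_index(d4, m = 5), "at least m")
  expect_error(morisita_index(d4, m = 2, deltas = 0.3), "divide the unit interval")
})

test_that("grid cell counts equal direct per-point binning", {
  set.seed(12)
  x <- matrix(runif(200 * 3), ncol = 3)
  mc <- morisita_index(x, m = 2, deltas = c(0.5, 0.25, 0.125))
  rng <- apply(x, 2, range)
  u <- sweep(sweep(x, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  for (i in seq_along(mc$deltas)) {
    del <- mc$deltas[i]
    cells <- pmin(floor(u / del), 1 / del - 1)
    key <- apply(cells, 1, paste, collapse = ",")
    expect_identical(sort(mc$cell_counts[[i]]), sort(as.integer(table(key))))
  }
})

test_that("index discriminates clustered, random and regular patterns", {
  set.seed(13)
  csr <- matrix(runif(2e4), ncol = 2)
  I_csr <- morisita_index(csr)$values
  expect_true(all(I_csr > 0.8 & I_csr < 1.2))

  blobs <- generate_fixture(synthetic_spec("blobs", 3000, seed = 2))
  expect_gt(max(morisita_index(blobs$coords)$values), 1.5)

  lattice <- generate_fixture(synthetic_spec("grid", 4096))
  I_lat <- morisita_index(lattice$coords)$values
  expect_lt(min(I_lat), 1)
})

test_that("intrinsic dimension recovers the manifold dimension", {
  set.seed(14)
  for (E in c(1, 2, 3)) {
    x <- matrix(runif(8000 * E), ncol = E)
    expect_equal(estimate_id(x)$id_value, E, tolerance = 0.3)
  }
  x <- runif(8000)
  expect_equal(estimate_id(cbind(x, x))$id_value, 1, tolerance = 0.2)
})

test_that("redundancy ranking keeps informative features and drops duplicates", {
  set.seed(15)
  xy <- cbind(x = runif(5000), y = runif(5000))
  rk <- rank_redundancy(cbind(xy, xcopy = xy[, 1]))
  expect_setequal(setdiff(rk$selected, "y"), intersect(rk$selected, c("x", "xcopy")))
  expect_length(rk$selected, 2)
  expect_true("y" %in% rk$selected)
  expect_true(all(diff(rk$id_trace[seq_along(rk$selected)]) >= 0.05 - 1e-9))

  single <- rank_redundancy(matrix(runif(2000), ncol = 1,
                                   dimnames = list(NULL, "only")))
  expect_identical(single$selected, "only")
  expect_length(single$id_trace, 1)
})
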