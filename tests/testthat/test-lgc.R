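test_that("growth-curve rows are exact hand counts and monotone", {
  two <- point_pattern(rbind(c(0, 0), c(500, 0)))
  g <- build_lgc(two, c(300, 600))
  expect_identical(unname(g$counts), matrix(c(0L, 0L, 1L, 1L), 2, 2))

  th <- generate_fixture(synthetic_spec("thomas", 1000, seed = 4))
  g2 <- build_lgc(th, make_radius_grid(0.01, 0.3, 8))
  expect_true(all(apply(g2$counts, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(g2$counts <= th$n - 1))
})

test_that("column means of the growth curves equal the sandbox curve exactly", {
  csr <- generate_csr(unit_square(), 3000, seed = 6)
  rg <- make_radius_grid(0.01, 0.1, 6)
  g <- build_lgc(csr, rg)
  sb <- sandbox_count(csr, rg)
  expect_equal(unname(colMeans(g$counts)), unname(sb$mean_counts), tolerance = 1e-12)
})

test_that("local fractal dimension matches area/length scaling and flags invalids", {
  csr <- generate_csr(unit_square(), 20000, seed = 2)
  g <- build_lgc(csr, make_radius_grid(0.005, 0.05, 10))
  fd <- local_fdim(g)
  expect_equal(mean(fd$fdim[fd$valid]), 2, tolerance = 0.1)

  line <- generate_fixture(synthetic_spec("line", 5000))
  gl <- build_lgc(line, make_radius_grid(0.002, 0.05, 8))
  fl <- local_fdim(gl)
  expect_equal(mean(fl$fdim[fl$valid]), 1, tolerance = 0.05)

  # three mutually distant points, radii too small to see a neighbor
  iso <- point_pattern(rbind(c(0, 0), c(10, 0), c(0, 10)))
  fi <- local_fdim(build_lgc(iso, c(0.5, 1, 2)))
  expect_false(any(fi$valid))
  expect_true(all(is.na(fi$fdim)))
})

test_that("clustered patterns have wider per-radius count spread than CSR", {
  rg <- make_radius_grid(0.01, 0.2, 8)
  th <- generate_fixture(synthetic_spec("thomas", 5000, seed = 8))
  cs <- generate_csr(unit_square(), 5000, seed = 9)
  iqr_t <- apply(build_lgc(th, rg)$counts, 2, stats::IQR)
  iqr_c <- apply(build_lgc(cs, rg)$counts, 2, stats::IQR)
  expect_true(all(iqr_t > iqr_c))
})

test_that("preprocessing transforms behave and drop constant columns", {
  th <- generate_fixture(synthetic_spec("thomas", 500, seed = 3))
  g <- build_lgc(th, make_radius_grid(0.02, 0.3, 5))
  raw <- preprocess(g, "raw")
  expect_equal(unname(raw$values), unname(g$counts) + 0.0)

  z <- preprocess(g, "zscore")
  expect_true(all(abs(colMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-9))

  m <- cbind(a = rnorm(100), b = rep(2, 100))
  expect_warning(fz <- preprocess(m, "zscore"), "zero-variance")
  expect_identical(fz$feature_names, "a")
  expect_identical(fz$dropped, "b")
})

test_that("PCA summary conserves variance and reflects redundancy", {
  set.seed(11)
  iso <- cbind(rnorm(5000), rnorm(5000))
  ps <- pca_summary(iso)
  expect_equal(ps$explained_fraction, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(ps$cumulative[length(ps$cumulative)], 1, tolerance = 1e-9)

  x <- rnorm(1000); y <- rnorm(1000)
  dup <- pca_summary(cbind(x, y, x))
  expect_equal(dup$explained_fraction[3], 0, tolerance = 1e-9)
  expect_true(all(diff(dup$cumulative) >= -1e-12))
})
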