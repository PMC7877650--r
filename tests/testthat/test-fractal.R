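test_that("log-log OLS is exact on power laws and masks zeros", {
  R <- c(1, 2, 4, 8)
  fit <- fit_loglog(R, 3 * R^1.5)
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, log(3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_equal(fit_loglog(R, rep(2, 4))$slope, 0, tolerance = 1e-12)

  vals <- c(0, 2, 4, 8, 16)
  fit0 <- fit_loglog(c(1, 2, 4, 8, 16), vals)
  expect_identical(fit0$used_mask, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(fit0$slope, 1, tolerance = 1e-12)
  expect_error(fit_loglog(c(1, 2), c(0, 0)), "at least 2")
})

test_that("radius grids include endpoints under both spacings", {
  g <- make_radius_grid(300, 10000, 25)
  expect_length(g$radii, 25)
  expect_equal(g$radii[c(1, 25)], c(300, 10000))
  expect_true(all(diff(g$radii) > 0))
  expect_equal(make_radius_grid(1, 4, 3)$radii, c(1, 2, 4))
  expect_equal(make_radius_grid(1, 3, 3, "linear")$radii, c(1, 2, 3))
  expect_error(make_radius_grid(5, 2, 3), "r_min < r_max")
})

test_that("box counting recovers limiting dimensions", {
  one <- point_pattern(cbind(0.3, 0.4))
  b1 <- box_count(one, scales = c(0.1, 0.2, 0.4))
  expect_identical(b1$counts, rep(1L, 3))
  expect_equal(b1$fb, 0)

  lattice <- generate_fixture(synthetic_spec("grid", 4096))
  expect_equal(box_count(lattice)$fb, 2, tolerance = 0.1)

  csr <- generate_csr(unit_square(), 20000, seed = 2)
  bc <- box_count(csr)
  expect_equal(bc$fb, 2, tolerance = 0.1)
  expect_true(all(diff(bc$counts) >= 0))  # scales stored decreasing
})

test_that("sandbox counts match hand counts and the 1-D scaling", {
  two <- point_pattern(rbind(c(0, 0), c(5, 0)))
  expect_warning(sb <- sandbox_count(two, c(1, 10)), "undefined")
  expect_equal(unname(sb$mean_counts), c(0, 1))
  expect_true(is.na(sb$fsb))

  line <- generate_fixture(synthetic_spec("line", 10000))
  sl <- sandbox_count(line, make_radius_grid(0.001, 0.05, 10))
  expect_equal(sl$fsb, 1, tolerance = 0.05)

  csr <- generate_csr(unit_square(), 20000, seed = 2)
  sc <- sandbox_count(csr, make_radius_grid(0.003, 0.04, 15))
  expect_equal(sc$fsb, 2, tolerance = 0.1)
  expect_true(all(diff(sc$mean_counts) >= 0))
  expect_error(sandbox_count(point_pattern(cbind(1, 1)), c(1, 2)), "at least 2")
})

test_that("grid-indexed neighbor counts equal the all-pairs oracle", {
  set.seed(3)
  for (n in c(50, 500)) {
    pat <- point_pattern(cbind(runif(n), runif(n)))
    rg <- make_radius_grid(0.01, 0.4, 9)
    expect_identical(unname(build_lgc(pat, rg)$counts),
                     unname(lgc_bruteforce(pat, rg)))
  }
  # clustered pattern stresses the cell index harder
  th <- generate_fixture(synthetic_spec("thomas", 400, seed = 6))
  rg <- make_radius_grid(0.005, 0.3, 7)
  expect_identical(unname(build_lgc(th, rg)$counts),
                   unname(lgc_bruteforce(th, rg)))
})

test_that("box and sandbox dimensions agree on known patterns", {
  sp <- generate_fixture(synthetic_spec("sierpinski", 40000, seed = 7))
  fb <- box_count(sp)$fb
  fsb <- sandbox_count(sp, make_radius_grid(0.003, 0.1, 20))$fsb
  expect_equal(fb, fsb, tolerance = 0.1)
  expect_equal(fsb, log(3) / log(2), tolerance = 0.08)
})
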