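test_that("Hopkins statistic separates uniform from clustered data", {
  set.seed(21)
  u <- matrix(runif(4000), ncol = 2)
  hu <- hopkins_stat(u, 100, seed = 42)
  expect_equal(hu$hopkins, 0.5, tolerance = 0.05)
  expect_identical(hu$verdict, "uniform")
  expect_identical(hopkins_stat(u, 100, seed = 42)$hopkins, hu$hopkins)

  bl <- generate_fixture(synthetic_spec("blobs", 2000, params = list(sd = 0.02),
                                        seed = 3))
  hb <- hopkins_stat(bl$coords, 100, seed = 7)
  expect_gt(hb$hopkins, 0.8)
  expect_identical(hb$verdict, "clusterable")
  expect_error(hopkins_stat(u, 5000), "2\\*sample")
})

test_that("index voting finds the blob count and flags unstructured data", {
  bl <- generate_fixture(synthetic_spec("blobs", 900, params = list(sd = 0.02),
                                        seed = 4))
  v <- vote_k(bl$coords, 2:6, seed = 5)
  expect_identical(v$majority_k, 3L)
  expect_true(all(v$index_votes >= 2 & v$index_votes <= 6))
  expect_named(v$scores, c("k", "silhouette", "calinski_harabasz",
                           "davies_bouldin", "gap", "elbow_wss"))

  set.seed(6)
  cloud <- matrix(rnorm(1200), ncol = 2)
  vc <- vote_k(cloud, 2:6, seed = 7)
  expect_lte(unname(vc$index_votes["gap"]), 3L)  # gap leans to few clusters
})

test_that("k-means and PAM recover separated blobs deterministically", {
  bl <- generate_fixture(synthetic_spec("blobs", 600, params = list(k = 2, sd = 0.02),
                                        seed = 8))
  truth <- attr(bl, "labels")
  km <- cluster_kmeans(bl$coords, 2, seed = 1)
  expect_equal(ari(km$labels, truth), 1)
  expect_identical(cluster_kmeans(bl$coords, 2, seed = 1)$labels, km$labels)

  pm <- cluster_pam(bl$coords, 2)
  expect_equal(ari(pm$labels, truth), 1)
  # medoids are data rows
  expect_true(all(pm$centers_or_medoids %in% bl$coords))
  # SWAP never worsens the BUILD objective
  expect_lte(pm$objective["swap"], pm$objective["build"] + 1e-12)
})

test_that("PAM with one cluster finds the exhaustive 1-medoid minimizer", {
  set.seed(10)
  m <- matrix(rnorm(600), ncol = 2)
  pm <- cluster_pam(m, 1)
  expect_identical(as.integer(pm$medoid_ids),
                   as.integer(which.min(rowSums(as.matrix(dist(m))))))
})

test_that("CLARA agrees with full-data PAM and clamps oversized samples", {
  bl <- generate_fixture(synthetic_spec("blobs", 2000, params = list(sd = 0.02),
                                        seed = 9))
  ca <- cluster_clara(bl$coords, 3, seed = 2)
  pm <- cluster_pam(bl$coords, 3)
  expect_gt(ari(ca$labels, pm$labels), 0.95)
  expect_identical(cluster_clara(bl$coords, 3, seed = 2)$labels, ca$labels)
  expect_warning(cluster_clara(bl$coords[1:30, ], 2, sample_size = 100, seed = 1),
                 "clamped")
})

test_that("hierarchical clustering merges nearest pairs first and cuts cleanly", {
  pts <- rbind(c(0, 0), c(0, 0.1), c(5, 5), c(5, 5.1))
  hr <- cluster_hierarchical(pts)
  # first two merges join the two tight pairs (leaves appear as negatives;
  # the order of equal-height merges is arbitrary)
  expect_true(all(hr$merge[1:2, ] < 0))
  first_two <- lapply(1:2, function(i) as.integer(sort(-hr$merge[i, ])))
  expect_true(any(vapply(first_two, identical, logical(1), c(1L, 2L))))
  expect_true(any(vapply(first_two, identical, logical(1), c(3L, 4L))))
  expect_setequal(hr$leaf_order, 1:4)
  expect_true(all(diff(hr$height) >= 0))

  bl <- generate_fixture(synthetic_spec("blobs", 400, params = list(k = 2, sd = 0.02),
                                        seed = 11))
  cut2 <- cut_dendrogram(cluster_hierarchical(bl$coords), 2, bl$coords)
  expect_equal(ari(cut2$labels, attr(bl, "labels")), 1)
  expect_error(cluster_hierarchical(matrix(0, 10001, 2)), "subsample")
})

test_that("SOM training converges and its clusters match blob structure", {
  bl <- generate_fixture(synthetic_spec("blobs", 900, params = list(sd = 0.02),
                                        seed = 12))
  m1 <- som_train(bl$coords, 1, 1, epochs = 20, seed = 3)
  expect_equal(unname(m1$codebook[1, ]), unname(colMeans(bl$coords)),
               tolerance = 0.05)

  mdl <- som_train(bl$coords, 10, 10, epochs = 30, seed = 4)
  expect_identical(som_train(bl$coords, 10, 10, epochs = 30, seed = 4)$codebook,
                   mdl$codebook)
  # quantization error is non-increasing over the late training phase
  tail_qe <- mdl$training_log[seq(ceiling(0.8 * 30), 30)]
  expect_true(all(diff(tail_qe) <= 1e-8))
  sc <- som_cluster(mdl, bl$coords, 3, seed = 5)
  expect_gt(ari(sc$labels, attr(bl, "labels")), 0.9)
  expect_error(som_cluster(m1, bl$coords, 3), "fewer units")
})

test_that("hexagonal grids offset odd rows", {
  mdl <- som_train(matrix(rnorm(200), ncol = 2), 2, 3, epochs = 2, seed = 1)
  pos <- mdl$grid$positions
  expect_equal(pos[4:6, 1] - pos[1:3, 1], rep(0.5, 3))
  expect_equal(unique(round(diff(unique(pos[, 2])), 9)), round(sqrt(3) / 2, 9))
})
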