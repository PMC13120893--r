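test_that("variance-peak subsampling finds strict interior maxima", {
  # build window vectors whose per-window variance is [1,3,2,5,4]
  X <- t(sapply(c(1, 3, 2, 5, 4), function(v) c(0, sqrt(v) * c(-1, 1))))
  expect_equal(apply(X, 1, var), c(1, 3, 2, 5, 4))
  expect_equal(subsample_variance_peaks(X), c(2L, 4L))

  mono <- t(sapply(1:5, function(v) c(0, sqrt(v) * c(-1, 1))))
  expect_warning(idx <- subsample_variance_peaks(mono), "no interior")
  expect_equal(idx, 1:5)

  # plateau contributes its first index only
  Xp <- t(sapply(c(1, 3, 3, 1, 2, 1), function(v) c(0, sqrt(v) * c(-1, 1))))
  expect_equal(subsample_variance_peaks(Xp), c(2L, 5L))
})

test_that("L1 k-means medians, separation and degenerate cases", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  km1 <- kmeans_l1(X, 1, n_replicates = 3, seed = 1)
  expect_equal(drop(km1$centroids), apply(X, 2, median), tolerance = 1e-12)

  blob1 <- matrix(rnorm(300, 0, 0.3), 100, 3)
  blob2 <- matrix(rnorm(300, 4, 0.3), 100, 3)
  km2 <- kmeans_l1(rbind(blob1, blob2), 2, n_replicates = 10, seed = 2)
  meds <- rbind(apply(blob1, 2, median), apply(blob2, 2, median))
  ord <- order(km2$centroids[, 1])
  expect_lt(max(abs(km2$centroids[ord, ] - meds)), 0.1)

  ident <- matrix(rep(c(0, 5, 9), each = 4), 12, 2)[rep(1:12), ]
  km3 <- kmeans_l1(ident, 3, n_replicates = 5, seed = 3)
  expect_equal(km3$inertia, 0)

  # determinism and best-of-replicates monotonicity under nested seeds
  kma <- kmeans_l1(rbind(blob1, blob2), 3, n_replicates = 5, seed = 9)
  kmb <- kmeans_l1(rbind(blob1, blob2), 3, n_replicates = 5, seed = 9)
  expect_identical(kma$centroids, kmb$centroids)
  kmc <- kmeans_l1(rbind(blob1, blob2), 3, n_replicates = 20, seed = 9)
  expect_lte(kmc$inertia, kma$inertia)
})

test_that("elbow selection maximises the discrete second difference", {
  expect_equal(elbow_select(c(10, 4, 3.5, 3.3, 3.2), 2:6), 3)
  expect_warning(k <- elbow_select(c(10, 8, 6, 4, 2), 2:6), "curvature")
  expect_equal(k, 2)
})

test_that("fixed-centroid assignment uses L1 with lowest-index ties", {
  C <- rbind(c(0, 0), c(4, 0), c(0, 4))
  expect_equal(assign_l1(C, C), 1:3, ignore_attr = TRUE)
  expect_equal(as.integer(assign_l1(matrix(c(2, 0), 1), C)), 1L)  # tie 1 vs 2
  expect_equal(as.integer(assign_l1(matrix(c(3.9, 0.2), 1), C)), 2L)
})

test_that("temporal metrics match run-length enumeration", {
  m <- temporal_metrics(c(3, 3, 3, 3), 4)
  expect_equal(m$fw, c(0, 0, 100, 0))
  expect_equal(m$mdt, c(NA, NA, 4, NA))
  expect_equal(m$nt, 0L)

  m2 <- temporal_metrics(c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(m2$fw, c(50, 50))
  expect_equal(m2$mdt, c(1.5, 3))
  expect_equal(m2$nt, 2L)
})

test_that("metric identities hold on random state vectors", {
  set.seed(13)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    W <- sample(20:200, 1)
    v <- sample.int(k, W, replace = TRUE)
    m <- temporal_metrics(v, k)
    expect_equal(sum(m$fw), 100, tolerance = 1e-9)
    expect_equal(m$nt, sum(diff(v) != 0))
    expect_equal(m$nt, sum(m$runs) - 1L)
    for (s in seq_len(k)) if (m$runs[s] > 0)
      expect_equal(m$fw[s] * W / 100, m$runs[s] * m$mdt[s],
                   tolerance = 1e-9)
    expect_lte(m$nt, W - 1)
  }
})

test_that("centroid contrasts are antisymmetric with Pearson similarity", {
  C <- rbind(rep(1, 10), rep(1, 10))
  cc <- centroid_contrasts(C)
  expect_equal(cc$differences$`1_minus_2`, rep(0, 10))
  expect_equal(cc$similarity[1, 2], 1)

  set.seed(14)
  C2 <- matrix(rnorm(3 * 903), 3, 903)
  cc2 <- centroid_contrasts(C2)
  expect_equal(cc2$differences$`1_minus_2`, -cc2$differences$`2_minus_1`)
  expect_lt(max(abs(cc2$similarity[upper.tri(cc2$similarity)])), 0.1)
})

test_that("top edges: ceiling count, ranking and deterministic ties", {
  set.seed(15)
  cent <- rnorm(903)                      # P = 43
  all_edges <- top_edges(cent, 1)
  expect_equal(nrow(all_edges), 903)
  top5 <- top_edges(cent, 0.05)
  expect_equal(nrow(top5), 46)            # ceiling(0.05 * 903)
  expect_equal(top5$z, cent[order(-abs(cent))][1:46])

  ties <- top_edges(rep(0.5, 15), 0.3)    # P = 6, all equal
  expect_equal(nrow(ties), 5)
  ij <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  expect_equal(cbind(ties$i, ties$j), unname(ij[1:5, ]))
})

test_that("state matching is the best-correlation permutation", {
  set.seed(16)
  ref <- matrix(rnorm(4 * 45), 4, 45)
  noisy <- ref[c(3, 1, 4, 2), ] + matrix(rnorm(4 * 45, 0, 0.1), 4, 45)
  m <- match_states(noisy, ref)
  expect_equal(m$matched_centroid, c(2, 4, 1, 3))
  expect_true(all(m$correlation > 0.9))
})
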