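test_that("the taper is a normalized, symmetric, unimodal profile", {
  tp <- build_taper(70, 3)
  w <- tp$weights
  expect_length(w, 70)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_equal(w[35], max(w), tolerance = 1e-12)  # peak plateau is central
  expect_true(all(diff(w[1:35]) >= -1e-15))       # rising to the centre

  flat <- build_taper(20, 1e-6)$weights
  expect_equal(flat, rep(1 / 20, 20), tolerance = 1e-6)
})

test_that("window counting follows floor arithmetic", {
  expect_equal(count_windows(2390, 70, 1), 2321L)
  expect_equal(count_windows(70, 70, 1), 1L)
  expect_equal(count_windows(100, 70, 10), 4L)
  expect_error(count_windows(69, 70), "window length")
})

test_that("weighted covariance matches its unweighted and analytic oracles", {
  set.seed(6)
  x <- rnorm(100)
  seg <- rbind(2 * x, -3 * x)        # perfectly (anti)correlated nodes
  w <- rep(1 / 100, 100)
  S <- weighted_covariance(seg, w)
  expect_equal(abs(S[1, 2]), sqrt(S[1, 1] * S[2, 2]), tolerance = 1e-12)

  seg2 <- matrix(rnorm(4 * 80), 4, 80)
  S2 <- weighted_covariance(seg2, rep(1 / 80, 80))
  oracle <- tcrossprod(seg2 - rowMeans(seg2)) / 80
  expect_equal(S2, oracle, tolerance = 1e-12)

  seg3 <- matrix(rnorm(2 * 500), 2, 500)
  S3 <- weighted_covariance(seg3, rep(1 / 500, 500))
  expect_lt(abs(cov2cor(S3)[1, 2]), 0.1)

  expect_error(weighted_covariance(rbind(x, 0 * x), w), "zero-variance")
})

test_that("graphical lasso matches inversion at zero penalty and empties at
           a saturating penalty", {
  expect_equal(glasso_precision(diag(4), 0), diag(4), tolerance = 1e-10)
  set.seed(7)
  A <- matrix(rnorm(60), 6, 10)
  S <- tcrossprod(A) / 10 + diag(0.3, 6)
  expect_lt(max(abs(glasso_precision(S, 0) - solve(S))), 1e-6)
  lam <- max(abs(S - diag(diag(S)))) * 1.001
  Theta <- glasso_precision(S, lam)
  expect_lt(max(abs(Theta[upper.tri(Theta)])), 1e-8)
  expect_equal(diag(Theta), 1 / diag(S), tolerance = 1e-8)
})

test_that("cross-validated penalty beats the grid endpoints on sparse truth", {
  set.seed(8)
  P <- 8
  Theta_true <- diag(P)
  Theta_true[cbind(1:7, 2:8)] <- Theta_true[cbind(2:8, 1:7)] <- 0.4
  S_true <- solve(Theta_true)
  X <- crossprod(chol(S_true), matrix(rnorm(P * 60), P, 60))
  ts <- subject_ts("cv", X)
  grid <- c(0.02, 0.1, 0.5, 2 / 0.9, 5)
  lam <- select_lambda(ts, grid = grid, folds = 4)
  scores <- attr(lam, "scores")
  expect_gte(scores[match(as.numeric(lam), grid)], scores[1])
  expect_gte(scores[match(as.numeric(lam), grid)], scores[length(grid)])
  expect_equal(as.numeric(select_lambda(ts, grid = 0.2, folds = 4)), 0.2)
})

test_that("precision-to-z applies Fisher's transform to the implied
           correlations", {
  expect_equal(precision_to_z(diag(3) * 2), matrix(0, 3, 3))
  # precision whose inverse has correlation exactly 0.5
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  z <- precision_to_z(solve(C))
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-4)
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)
  expect_identical(z, t(z))
})

test_that("the window stack is stable under stationarity and matches the
           Pearson oracle at vanishing penalty", {
  ts <- stationary_subject(P = 6, T = 200, seed = 10)
  taper <- build_taper(70, 3)
  dc <- compute_dynamic_connectome(ts, taper, window_config(lambda = 0))
  expect_equal(dim(dc$z_stack), c(131, 6, 6))
  V <- connectome_vectors(dc)
  cors <- cor(t(V))
  expect_gt(min(cors), 0.5)

  # oracle: Fisher-z of the taper-weighted Pearson correlations
  seg <- ts$data[, 1:70]
  S <- weighted_covariance(seg, taper$weights)
  z_oracle <- atanh(pmin(pmax(cov2cor(S), -1 + 1e-7), 1 - 1e-7))
  diag(z_oracle) <- 0
  expect_equal(dc$z_stack[1, , ], z_oracle, tolerance = 1e-4)

  one <- compute_dynamic_connectome(
    subject_ts("w1", ts$data[, 1:70]), taper, window_config(lambda = 0.1))
  expect_equal(dim(one$z_stack)[1], 1)
})

test_that("node permutation permutes every z-slice identically", {
  ts <- stationary_subject(P = 5, T = 120, seed = 11)
  taper <- build_taper(40, 3)
  cfgw <- window_config(lambda = 0.1)
  dc <- compute_dynamic_connectome(ts, taper, cfgw)
  perm <- c(3, 1, 5, 2, 4)
  tsp <- subject_ts(ts$subject_id, ts$data[perm, ])
  dcp <- compute_dynamic_connectome(tsp, taper, cfgw)
  for (w in c(1, 40, 81))
    expect_equal(dcp$z_stack[w, , ], dc$z_stack[w, perm, perm],
                 tolerance = 1e-6)
  expect_true(all(is.finite(dc$z_stack)))
})
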