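test_that("sparsity binarization keeps the floor(s*E) strongest edges", {
  set.seed(17)
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.9, -0.8, 0.1, 0.7, 0.2, 0.3)
  z <- z + t(z)
  adj <- binarize_at_sparsity(z, 0.5)
  expect_equal(sum(adj) / 2, 3)
  kept <- abs(z[upper.tri(z)])[adj[upper.tri(adj)] == 1]
  expect_setequal(kept, c(0.9, 0.8, 0.7))

  full <- binarize_at_sparsity(z, 0.999)       # floor(.999*6) = 5 edges
  expect_equal(sum(full) / 2, 5)
  expect_warning(binarize_at_sparsity(matrix(0, 4, 4), 0.5), "all-zero")
})

test_that("efficiency metrics reproduce closed-form graphs", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(nodal_efficiency(K4), rep(1, 4))
  expect_equal(local_efficiency(K4), rep(1, 4))

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(nodal_efficiency(star, 1), 1)
  expect_equal(nodal_efficiency(star, 2), 2 / 3)
  expect_equal(local_efficiency(star, 1), 0)   # leaves mutually unlinked
  expect_equal(local_efficiency(star, 2), 0)   # degree-1 convention

  iso <- diag(0L, 5)
  expect_equal(nodal_efficiency(iso), rep(0, 5))
})

test_that("efficiencies match the Floyd-Warshall oracle and are monotone
           under edge addition", {
  set.seed(18)
  for (rep in 1:300) {
    n <- sample(2:7, 1)
    adj <- random_adjacency(n, runif(1))
    expect_equal(nodal_efficiency(adj), fw_nodal_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(adj), fw_local_efficiency(adj),
                 tolerance = 1e-12)
    expect_true(all(nodal_efficiency(adj) >= 0 & nodal_efficiency(adj) <= 1))
    expect_true(all(local_efficiency(adj) >= 0 & local_efficiency(adj) <= 1))
  }
  # nodal efficiency is monotone under edge addition
  for (rep in 1:20) {
    adj <- random_adjacency(6, 0.3)
    free <- which(upper.tri(adj) & adj == 0)
    if (!length(free)) next
    e <- free[sample.int(length(free), 1)]
    adj2 <- adj
    adj2[e] <- 1L
    adj2[lower.tri(adj2)] <- t(adj2)[lower.tri(adj2)]
    expect_true(all(nodal_efficiency(adj2) >= nodal_efficiency(adj) - 1e-12))
  }
})

test_that("AUC over sparsity is the trapezoid rule, hence linear", {
  grid <- seq(0.1, 0.34, by = 0.01)
  expect_equal(auc_over_sparsity(rep(3, length(grid)), grid), 3 * 0.24,
               tolerance = 1e-12)
  expect_equal(auc_over_sparsity(c(0, 1), c(0, 1)), 0.5)
  set.seed(19)
  x <- rnorm(length(grid)); y <- rnorm(length(grid))
  manual <- sum(diff(grid) * (head(x, -1) + tail(x, -1)) / 2)
  expect_equal(auc_over_sparsity(x, grid), manual, tolerance = 1e-12)
  expect_equal(auc_over_sparsity(2 * x + 5 * y, grid),
               2 * auc_over_sparsity(x, grid) +
                 5 * auc_over_sparsity(y, grid), tolerance = 1e-10)
  expect_error(auc_over_sparsity(x[-1], grid), "length")
})

test_that("temporal CV is SD over mean with the stated conventions", {
  expect_equal(temporal_cv(rep(4, 10)), 0)
  expect_equal(temporal_cv(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(temporal_cv(c(1, 3)), 0.7071, tolerance = 1e-4)
  set.seed(20)
  x <- abs(rnorm(30)) + 1
  expect_equal(temporal_cv(7 * x), temporal_cv(x), tolerance = 1e-12)
  expect_warning(bad <- temporal_cv(c(-2, 1)), "mean")
  expect_true(is.na(bad))
  expect_error(temporal_cv(5, ddof = 1), "at least 2")
  expect_equal(temporal_cv(c(1, 3), ddof = 0), 0.5)
})

test_that("subject-level topological variability has the stated structure", {
  set.seed(21)
  zA <- matrix(0, 6, 6); zA[upper.tri(zA)] <- rnorm(15); zA <- zA + t(zA)
  zB <- matrix(0, 6, 6); zB[upper.tri(zB)] <- rnorm(15); zB <- zB + t(zB)
  cfg <- topology_config(sparsity_grid = seq(0.2, 0.4, by = 0.05))

  same <- structure(list(subject_id = "s", z_stack = array(
    rep(zA, each = 4), c(4, 6, 6))), class = "dynamic_connectome")
  tv <- topology_variability(same, cfg)
  expect_true(all(tv$cv$cv[!is.na(tv$cv$cv)] == 0))

  alt <- structure(list(subject_id = "s", z_stack = array(0, c(4, 6, 6))),
                   class = "dynamic_connectome")
  for (w in 1:4) alt$z_stack[w, , ] <- if (w %% 2) zA else zB
  tva <- topology_variability(alt, cfg)
  a <- apply(window_topology(zA, cfg)$nodal_efficiency, 1,
             auc_over_sparsity, grid = cfg$sparsity_grid)
  b <- apply(window_topology(zB, cfg)$nodal_efficiency, 1,
             auc_over_sparsity, grid = cfg$sparsity_grid)
  # two alternating values: closed-form CV of (a,b,a,b)
  cv_ref <- vapply(seq_len(6), function(i) {
    v <- c(a[i], b[i], a[i], b[i])
    sd(v) / mean(v)
  }, numeric(1))
  got <- tva$cv$cv[tva$cv$metric == "nodal_efficiency"]
  expect_equal(got, cv_ref, tolerance = 1e-12)
})
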