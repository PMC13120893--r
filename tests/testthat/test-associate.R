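test_that("partial correlation matches the residualize-then-correlate
           oracle", {
  # 6-point fixture with one covariate
  x <- c(1.2, 0.4, 2.5, 3.1, 1.9, 2.2)
  y <- c(0.8, 0.2, 1.9, 3.5, 1.1, 2.4)
  cv <- c(10, 12, 9, 14, 11, 13)
  pp <- partial_pearson(x, y, cv)
  rx <- residuals(lm(x ~ cv))
  ry <- residuals(lm(y ~ cv))
  expect_equal(pp$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(pp$n, 6)
  tval <- pp$r * sqrt((6 - 3) / (1 - pp$r^2))
  expect_equal(pp$p, 2 * pt(-abs(tval), 3), tolerance = 1e-12)

  # symmetry in x and y
  qq <- partial_pearson(y, x, cv)
  expect_identical(pp$r, qq$r)

  # covariate orthogonal to both: reduces to the plain correlation
  set.seed(22)
  x2 <- rnorm(50); y2 <- 0.5 * x2 + rnorm(50)
  c2 <- rnorm(50)
  c2 <- c2 - drop(qr.fitted(qr(cbind(1, x2, y2)), c2))
  expect_equal(partial_pearson(x2, y2, c2)$r, cor(x2, y2),
               tolerance = 1e-10)
  expect_equal(partial_pearson(x2, x2, rnorm(50))$r, 1, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule and is permutation
           stable", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(23)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_metric_fixture <- function(n = 40, k = 4, seed = 24, effect = 0) {
  set.seed(seed)
  cohort <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:n),
    bmi = runif(n, 17, 40), age = sample(22:37, n, TRUE),
    gender = sample(c("male", "female"), n, TRUE))
  by_state <- do.call(rbind, lapply(1:k, function(s) tibble::tibble(
    subject_id = cohort$subject_id, state = s,
    fw = runif(n, 10, 40),
    mdt = runif(n, 2, 20) + if (s == 3) effect * cohort$bmi else 0,
    runs = sample(3:10, n, TRUE))))
  by_subject <- tibble::tibble(subject_id = cohort$subject_id,
                               nt = sample(10:40, n, TRUE),
                               n_windows = 100)
  list(metrics = list(by_state = by_state, by_subject = by_subject),
       cohort = cohort)
}

test_that("state-metric association builds the corrected family as
           specified", {
  fx <- make_metric_fixture(effect = 1)
  res <- associate_state_metrics(fx$metrics, fx$cohort)
  fam <- res[res$family == "fw_mdt", ]
  expect_equal(nrow(fam), 8)                   # 2 metrics x 4 states
  expect_true(all(fam$p_corr >= fam$p_raw))
  r3 <- fam$r[fam$state == 3 & fam$metric == "MDT"]
  expect_gt(r3, 0)
  expect_lt(fam$p_corr[fam$state == 3 & fam$metric == "MDT"], 0.05)
  expect_equal(nrow(res[res$family == "nt", ]), 1)
  # separate families: FW and MDT corrected independently
  sep <- associate_state_metrics(fx$metrics, fx$cohort,
                                 family = "separate")
  expect_setequal(unique(sep$family), c("fw", "mdt", "nt"))
  expect_equal(sum(sep$family == "fw"), 4)
})

test_that("unvisited states are dropped pairwise, small tests skipped", {
  fx <- make_metric_fixture()
  fx$metrics$by_state$mdt[fx$metrics$by_state$state == 2][1:5] <- NA
  res <- associate_state_metrics(fx$metrics, fx$cohort)
  expect_equal(res$n[res$state == 2 & res$metric == "MDT"], 35)
  expect_equal(res$n[res$state == 2 & res$metric == "FW"], 40)
})

test_that("group contrasts are Welch t-tests with the stated sign
           convention", {
  fx <- make_metric_fixture(n = 120, seed = 25)
  # plant: healthy subjects get lower MDT in state 3
  grp <- assign_bmi_group(fx$cohort$bmi)
  sel <- fx$metrics$by_state$state == 3
  healthy_ids <- fx$cohort$subject_id[grp == "healthy"]
  hrows <- sel & fx$metrics$by_state$subject_id %in% healthy_ids
  fx$metrics$by_state$mdt[hrows] <- fx$metrics$by_state$mdt[hrows] - 8
  res <- group_contrasts(fx$metrics, fx$cohort)
  expect_setequal(unique(res$contrast),
                  c("healthy_vs_overweight", "healthy_vs_obese"))
  t3 <- res$t[res$state == 3 & res$metric == "MDT"]
  expect_true(all(t3 < 0))

  # closed-form Welch oracle
  h <- fx$metrics$by_state$mdt[hrows]
  comp_ids <- fx$cohort$subject_id[grp == "obese"]
  o <- fx$metrics$by_state$mdt[sel &
                                 fx$metrics$by_state$subject_id %in%
                                 comp_ids]
  tw <- (mean(h) - mean(o)) / sqrt(var(h) / length(h) + var(o) / length(o))
  expect_equal(res$t[res$contrast == "healthy_vs_obese" & res$state == 3 &
                       res$metric == "MDT"], tw, tolerance = 1e-10)

  same <- t.test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
})

test_that("topology association corrects per metric and reports
           degenerate columns", {
  set.seed(26)
  n <- 30; P <- 5
  cohort <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                           bmi = runif(n, 18, 38),
                           age = sample(22:37, n, TRUE),
                           gender = sample(c("male", "female"), n, TRUE))
  tv_list <- lapply(seq_len(n), function(i) {
    cv <- tibble::tibble(
      subject_id = cohort$subject_id[i],
      node = rep(1:P, 2),
      metric = rep(c("nodal_efficiency", "local_efficiency"), each = P),
      cv = runif(2 * P, 0.2, 0.6))
    # node 1 nodal CV decreases with BMI; node 5 local CV constant
    cv$cv[1] <- 0.8 - 0.015 * cohort$bmi[i]
    cv$cv[cv$node == 5 & cv$metric == "local_efficiency"] <- 0.3
    structure(list(cv = cv), class = "topology_variability")
  })
  expect_message(res <- associate_topology(tv_list, cohort), "degenerate")
  expect_equal(attr(res, "excluded"), "local_efficiency:node5")
  expect_equal(sum(res$family == "nodal_efficiency"), 5)
  expect_equal(sum(res$family == "local_efficiency"), 4)
  r1 <- res$r[res$node == 1 & res$metric == "nodal_efficiency"]
  expect_lt(r1, 0)
  expect_lt(res$p_corr[res$node == 1 & res$metric == "nodal_efficiency"],
            0.05)
})
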