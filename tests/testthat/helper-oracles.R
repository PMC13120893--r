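# Independent oracles and small fixture builders used across test files.

# Floyd-Warshall all-pairs shortest paths (matrix form, Inf = unreachable)
fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# nodal efficiency oracle from Floyd-Warshall distances
fw_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(rep(0, n))
  D <- fw_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# local efficiency oracle: Floyd-Warshall on each neighbour-induced subgraph
fw_local_efficiency <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0 & seq_len(n) != i)
    if (length(nb) < 2) next
    sub <- adj[nb, nb, drop = FALSE]
    D <- fw_distances(sub)
    inv <- 1 / D
    diag(inv) <- 0
    out[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  out
}

random_adjacency <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p_edge)
  adj + t(adj)
}

# tiny stationary subject for dFC tests: one covariance state, no
# switching; defaults to the block-structured visual-dominant state so the
# edge pattern is heterogeneous
stationary_subject <- function(P = 6, T = 300, seed = 7, Sigma = NULL) {
  set.seed(seed)
  if (is.null(Sigma)) {
    Sigma <- if (P >= 6) default_state_covariances(P)[[3]]
    else {
      S <- matrix(0.5, P, P); diag(S) <- 1; S
    }
  }
  subject_ts("stat01", crossprod(chol(Sigma), matrix(rnorm(P * T), P, T)))
}

# small simulated cohort shared by slower integration tests
tiny_cohort <- function(n = 4, T = 250, seed = 5, ...) {
  simulate_cohort(sim_config(n_subjects = n, n_timepoints = T, seed = seed,
                             ...))
}
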