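#' Select exemplar windows at local maxima of connectivity variance
#'
#' Computes the variance of each window's upper-triangle z-values and
#' returns the indices of strict interior local maxima of that variance
#' series (a plateau contributes its first index only; endpoints are
#' excluded). If no interior peak exists, all windows are returned with a
#' warning.
#'
#' @param dc a [compute_dynamic_connectome()] result, or a `W x E` matrix
#'   of window vectors.
#' @return integer vector of window indices.
#' @export
subsample_variance_peaks <- function(dc) {
  X <- if (inherits(dc, "dynamic_connectome")) connectome_vectors(dc) else dc
  W <- nrow(X)
  if (W < 3) {
    warning("fewer than 3 windows; returning all")
    return(seq_len(W))
  }
  v <- apply(X, 1, var)
  r <- rle(v)
  nruns <- length(r$values)
  starts <- cumsum(c(1, r$lengths))[seq_len(nruns)]
  peaks <- integer(0)
  if (nruns >= 3)
    for (m in 2:(nruns - 1))
      if (r$values[m] > r$values[m - 1] && r$values[m] > r$values[m + 1])
        peaks <- c(peaks, starts[m])
  if (!length(peaks)) {
    warning("no interior variance peaks; returning all windows")
    return(seq_len(W))
  }
  peaks
}

#' k-means clustering under the L1 (Manhattan) distance
#'
#' Assignment by minimum cityblock distance with lowest-index tie-break;
#' centroid update by component-wise median; empty clusters are re-seeded
#' at the point currently farthest from its centroid. The best of
#' `n_replicates` random initialisations (by total L1 inertia) is kept.
#' Deterministic given `seed`.
#'
#' @param X `n x d` matrix of observations.
#' @param k number of clusters (`k <= n`).
#' @param n_replicates random restarts (default 100).
#' @param seed RNG seed for the initial centroid draws; `NULL` uses the
#'   current RNG state.
#' @param maxit iteration cap per replicate.
#' @return list with `centroids` (`k x d`), `labels`, `inertia`,
#'   `replicate_inertia`.
#' @export
kmeans_l1 <- function(X, k, n_replicates = 100, seed = NULL, maxit = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 1, n >= k)
  if (!is.null(seed)) set.seed(seed)
  init <- t(replicate(n_replicates, sample.int(n, k)))
  if (k == 1) init <- matrix(init, ncol = 1)
  res <- cpp_kmeans_l1(X, k, init - 1L, maxit)
  res$centroids <- matrix(res$centroids, nrow = k)
  res$labels <- as.integer(res$labels)
  res
}

#' Assign observations to fixed centroids by L1 distance
#'
#' Single assignment pass (no centroid update); ties go to the lowest
#' centroid index.
#'
#' @param X `n x d` matrix.
#' @param centroids `k x d` matrix.
#' @return integer labels in `1..k` with the distances in the `dist`
#'   attribute.
#' @export
assign_l1 <- function(X, centroids) {
  res <- cpp_assign_l1(as.matrix(X), as.matrix(centroids))
  out <- as.integer(res$labels)
  attr(out, "dist") <- as.numeric(res$dist)
  out
}

#' Cluster validity index: within/between L1 dispersion ratio
#'
#' @param X observation matrix.
#' @param labels cluster labels.
#' @param centroids centroid matrix.
#' @return mean within-cluster L1 distance to the assigned centroid
#'   divided by the mean pairwise between-centroid L1 distance.
#' @export
cluster_validity <- function(X, labels, centroids) {
  X <- as.matrix(X)
  within <- mean(vapply(seq_len(nrow(X)), function(i)
    sum(abs(X[i, ] - centroids[labels[i], ])), numeric(1)))
  k <- nrow(centroids)
  if (k < 2) return(NA_real_)
  pairs <- utils::combn(k, 2)
  between <- mean(apply(pairs, 2, function(p)
    sum(abs(centroids[p[1], ] - centroids[p[2], ]))))
  within / between
}

#' Elbow selection over a cluster-validity curve
#'
#' Picks the `k` with the greatest curvature, operationalised as the
#' maximum discrete second difference of the validity curve; ties go to
#' the smaller `k`. A (numerically) flat or linear curve yields the
#' smallest `k` with a warning.
#'
#' @param validity_curve validity values, one per candidate `k`.
#' @param k_values the candidate `k` values (default consecutive integers
#'   starting at 2).
#' @return the selected `k`.
#' @export
elbow_select <- function(validity_curve, k_values = NULL) {
  m <- length(validity_curve)
  if (m < 3) stop("need a validity curve over at least 3 values of k")
  if (is.null(k_values)) k_values <- seq(2, length.out = m)
  d2 <- validity_curve[1:(m - 2)] - 2 * validity_curve[2:(m - 1)] +
    validity_curve[3:m]
  tol <- 1e-10 * max(1, max(abs(validity_curve)))
  if (max(d2) <= tol) {
    warning("no curvature in the validity curve; returning smallest k")
    return(k_values[1])
  }
  k_values[which.max(d2) + 1]
}

#' Identify recurring connectivity states across a cohort
#'
#' Concatenates each subject's variance-peak exemplar windows, scans
#' candidate `k` by L1 k-means and selects `k` by the elbow criterion on
#' the within/between validity curve (or uses a fixed `k`), then assigns
#' every window of every subject to the nearest final centroid in a single
#' pass (optionally with further k-means refinement).
#'
#' @param dc_list list of [compute_dynamic_connectome()] results.
#' @param k_range candidate numbers of states (default `2:10`); ignored
#'   when `k` is given.
#' @param k fixed number of states, bypassing the elbow scan.
#' @param n_replicates k-means restarts for the final solution (default
#'   100).
#' @param scan_replicates restarts during the elbow scan (default
#'   `n_replicates`).
#' @param seed RNG seed.
#' @param refine if `TRUE`, run full k-means on all windows initialised at
#'   the exemplar centroids instead of a single assignment pass.
#' @return object of class `state_model`: `k`, `centroids` (`k x E`),
#'   per-subject `assignments`, `subsample_index`, `validity_curve`,
#'   `k_range`, `subject_ids`.
#' @export
identify_states <- function(dc_list, k_range = 2:10, k = NULL,
                            n_replicates = 100,
                            scan_replicates = n_replicates, seed = 1,
                            refine = FALSE) {
  vecs <- lapply(dc_list, connectome_vectors)
  idx <- lapply(vecs, subsample_variance_peaks)
  exemplars <- do.call(rbind, Map(function(v, i) v[i, , drop = FALSE],
                                  vecs, idx))
  validity <- NULL
  if (is.null(k)) {
    fits <- vector("list", length(k_range))
    validity <- numeric(length(k_range))
    for (j in seq_along(k_range)) {
      fits[[j]] <- kmeans_l1(exemplars, k_range[j], scan_replicates,
                             seed = seed + k_range[j])
      validity[j] <- cluster_validity(exemplars, fits[[j]]$labels,
                                      fits[[j]]$centroids)
    }
    k <- elbow_select(validity, k_range)
  }
  fit <- kmeans_l1(exemplars, k, n_replicates, seed = seed)
  centroids <- fit$centroids
  assignments <- lapply(vecs, function(v) assign_l1(v, centroids))
  if (refine) {
    # iterate full k-means on all windows from the exemplar centroids
    all_windows <- do.call(rbind, vecs)
    ref <- refine_from(all_windows, centroids)
    centroids <- ref$centroids
    splits <- rep(seq_along(vecs), vapply(vecs, nrow, integer(1)))
    assignments <- split(ref$labels, splits)
  }
  structure(list(k = k, centroids = centroids, assignments = assignments,
                 subsample_index = idx, validity_curve = validity,
                 k_range = if (is.null(validity)) NULL else k_range,
                 subject_ids = vapply(dc_list, `[[`, character(1),
                                      "subject_id")),
            class = "state_model")
}

# full k-means iterations from fixed starting centroids
refine_from <- function(X, centroids, maxit = 100) {
  k <- nrow(centroids)
  labels <- assign_l1(X, centroids)
  for (it in seq_len(maxit)) {
    new_c <- centroids
    for (c in seq_len(k)) {
      members <- which(labels == c)
      if (length(members))
        new_c[c, ] <- apply(X[members, , drop = FALSE], 2, median)
    }
    new_labels <- assign_l1(X, new_c)
    centroids <- new_c
    if (all(new_labels == labels)) break
    labels <- new_labels
  }
  list(centroids = centroids, labels = as.integer(labels))
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model: k = %d, %d subjects, %d-edge centroids>\n",
              x$k, length(x$assignments), ncol(x$centroids)))
  invisible(x)
}

#' Temporal metrics of one state-transition vector
#'
#' Fractional window (FW, percent of windows per state), mean dwell time
#' (MDT, mean maximal-run length per state, `NA` for unvisited states) and
#' number of transitions (NT, count of adjacent label changes).
#'
#' @param state_vector integer labels in `1..k`.
#' @param k number of states.
#' @return list with `fw` (length-`k`, percent), `mdt` (length-`k`,
#'   windows), `nt` (scalar), `runs` (runs per state).
#' @export
temporal_metrics <- function(state_vector, k) {
  stopifnot(all(state_vector >= 1), all(state_vector <= k))
  W <- length(state_vector)
  r <- rle(as.integer(state_vector))
  fw <- 100 * tabulate(state_vector, k) / W
  mdt <- rep(NA_real_, k)
  runs <- integer(k)
  for (s in seq_len(k)) {
    len <- r$lengths[r$values == s]
    runs[s] <- length(len)
    if (length(len)) mdt[s] <- mean(len)
  }
  list(fw = fw, mdt = mdt, nt = length(r$lengths) - 1L, runs = runs)
}

#' Per-subject state temporal metrics for a cohort
#'
#' @param model a [identify_states()] result.
#' @return list of tibbles: `by_state` (`subject_id`, `state`, `fw`,
#'   `mdt`, `runs`) and `by_subject` (`subject_id`, `nt`, `n_windows`).
#' @export
state_metrics <- function(model) {
  per <- lapply(seq_along(model$assignments), function(i) {
    m <- temporal_metrics(model$assignments[[i]], model$k)
    list(by_state = tibble::tibble(
      subject_id = model$subject_ids[i], state = seq_len(model$k),
      fw = m$fw, mdt = m$mdt, runs = m$runs),
      by_subject = tibble::tibble(
        subject_id = model$subject_ids[i], nt = m$nt,
        n_windows = length(model$assignments[[i]])))
  })
  list(by_state = do.call(rbind, lapply(per, `[[`, "by_state")),
       by_subject = do.call(rbind, lapply(per, `[[`, "by_subject")))
}

#' Pairwise centroid differences and pattern similarity
#'
#' @param model a [identify_states()] result (or any `k x E` centroid
#'   matrix).
#' @return list with `differences` (named list of `a_minus_b` vectors) and
#'   `similarity` (`k x k` Pearson correlation of centroid vectors).
#' @export
centroid_contrasts <- function(model) {
  C <- if (inherits(model, "state_model")) model$centroids else model
  k <- nrow(C)
  stopifnot(k >= 2)
  diffs <- list()
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b)
    diffs[[sprintf("%d_minus_%d", a, b)]] <- C[a, ] - C[b, ]
  sim <- suppressWarnings(cor(t(C)))
  for (a in seq_len(k)) for (b in seq_len(k))
    if (identical(C[a, ], C[b, ])) sim[a, b] <- 1
  list(differences = diffs, similarity = sim)
}

#' Strongest edges of a state centroid
#'
#' Edges ranked by `|z|` descending with deterministic ties (upper-triangle
#' column-major index order); the top `ceiling(fraction * E)` are returned.
#'
#' @param centroid length-`E` vector of upper-triangle z-values.
#' @param fraction fraction of edges to keep (default 0.05).
#' @return tibble with node indices `i`, `j`, the signed `z` value and the
#'   rank.
#' @export
top_edges <- function(centroid, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  E <- length(centroid)
  P <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
  if (P * (P - 1) / 2 != E) stop("centroid length is not P(P-1)/2")
  ij <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  ord <- order(-abs(centroid))  # stable: ties keep index order
  n_top <- as.integer(ceiling(fraction * E))
  sel <- ord[seq_len(n_top)]
  tibble::tibble(i = ij[sel, 1], j = ij[sel, 2], z = centroid[sel],
                 rank = seq_len(n_top))
}

#' Match recovered centroids to reference state patterns
#'
#' Finds the assignment of recovered centroids to reference patterns that
#' maximises the total Pearson correlation (exhaustive over permutations
#' for up to 8 states, greedy beyond).
#'
#' @param centroids `k x E` recovered centroid matrix.
#' @param reference `k0 x E` reference pattern matrix (`k0 <= k`).
#' @return tibble with `reference`, `matched_centroid`, `correlation`.
#' @export
match_states <- function(centroids, reference) {
  R <- cor(t(reference), t(centroids))  # k0 x k
  k0 <- nrow(R); k <- ncol(R)
  stopifnot(k0 <= k)
  if (k <= 8) {
    perms <- permutations_of(k, k0)
    best <- perms[[which.max(vapply(perms, function(p)
      sum(R[cbind(seq_len(k0), p)]), numeric(1)))]]
  } else {
    best <- integer(k0)
    Rw <- R
    for (s in seq_len(k0)) {
      j <- which.max(Rw[s, ])
      best[s] <- j
      Rw[, j] <- -Inf
    }
  }
  tibble::tibble(reference = seq_len(k0), matched_centroid = best,
                 correlation = R[cbind(seq_len(k0), best)])
}

# all injective maps 1..m -> 1..n as a list of integer vectors
permutations_of <- function(n, m = n) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (j in seq_len(n)) {
    rest <- permutations_of(n, m - 1)
    for (r in rest) if (!j %in% r) out[[length(out) + 1]] <- c(j, r)
  }
  out
}

#' Group-averaged state centroids and cross-group consistency
#'
#' A subject-specific centroid for a state is the mean of that subject's
#' window vectors assigned to the state (subjects with no windows in a
#' state are excluded from that state's average). Group centroids average
#' subject-specific centroids within each group; consistency is the
#' Pearson correlation of group centroids per state across group pairs.
#'
#' @param dc_list list of dynamic connectomes (order matching the model).
#' @param model a [identify_states()] result.
#' @param groups factor/character vector, one group label per subject.
#' @return list with `group_centroids` (list by group of `k x E`
#'   matrices) and `similarity` (list by state of group-pair correlation
#'   matrices).
#' @export
group_centroids <- function(dc_list, model, groups) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == length(dc_list))
  subj_cent <- lapply(seq_along(dc_list), function(i) {
    v <- connectome_vectors(dc_list[[i]])
    lab <- model$assignments[[i]]
    t(vapply(seq_len(model$k), function(s) {
      if (any(lab == s)) colMeans(v[lab == s, , drop = FALSE])
      else rep(NA_real_, ncol(v))
    }, numeric(ncol(v))))
  })
  lev <- levels(groups)
  gc <- lapply(lev, function(g) {
    members <- subj_cent[groups == g]
    if (!length(members)) stop("empty group: ", g)
    out <- matrix(NA_real_, model$k, ncol(members[[1]]))
    for (s in seq_len(model$k)) {
      rows <- do.call(rbind, lapply(members, function(m) m[s, ]))
      rows <- rows[stats::complete.cases(rows), , drop = FALSE]
      if (nrow(rows)) out[s, ] <- colMeans(rows)
    }
    out
  })
  names(gc) <- lev
  sim <- lapply(seq_len(model$k), function(s) {
    M <- do.call(rbind, lapply(gc, function(m) m[s, ]))
    cor(t(M), use = "pairwise.complete.obs")
  })
  list(group_centroids = gc, similarity = sim)
}

#' Re-run state identification over alternative cluster numbers
#'
#' For each `k` in `k_list`, repeats clustering (fixed `k`), window
#' assignment and temporal metrics, and reports the best-match centroid
#' similarity to a primary solution.
#'
#' @param dc_list list of dynamic connectomes.
#' @param primary the primary [identify_states()] model.
#' @param k_list alternative cluster numbers.
#' @param n_replicates,seed as in [identify_states()].
#' @return named list by `k`, each with `model`, `metrics` and `match`
#'   (similarity of each primary centroid to its best alternative match).
#' @export
robustness_over_k <- function(dc_list, primary, k_list = c(3, 5, 6),
                              n_replicates = 100, seed = 1) {
  out <- lapply(k_list, function(kk) {
    model <- identify_states(dc_list, k = kk, n_replicates = n_replicates,
                             seed = seed)
    R <- cor(t(primary$centroids), t(model$centroids))
    list(model = model, metrics = state_metrics(model),
         match = tibble::tibble(primary_state = seq_len(primary$k),
                                best_match = apply(R, 1, which.max),
                                correlation = apply(R, 1, max)))
  })
  names(out) <- paste0("k", k_list)
  out
}
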