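#' Topology configuration
#'
#' @param sparsity_grid ascending fractions in (0, 1) of strongest edges
#'   retained when binarizing (default 0.10-0.34 in steps of 0.01).
#' @param metrics subset of `c("nodal_efficiency", "local_efficiency")`.
#' @param cv_ddof degrees-of-freedom correction for the temporal SD (1 =
#'   sample SD, the default).
#' @param rank_by `"absolute"` (default) ranks edges by `|z|`;
#'   `"positive"` ranks by signed value.
#' @return object of class `topology_config`.
#' @export
topology_config <- function(sparsity_grid = seq(0.10, 0.34, by = 0.01),
                            metrics = c("nodal_efficiency",
                                        "local_efficiency"),
                            cv_ddof = 1, rank_by = c("absolute",
                                                     "positive")) {
  stopifnot(length(sparsity_grid) >= 1, all(sparsity_grid > 0),
            all(sparsity_grid < 1), !is.unsorted(sparsity_grid,
                                                 strictly = TRUE),
            cv_ddof %in% c(0, 1))
  metrics <- match.arg(metrics, c("nodal_efficiency", "local_efficiency"),
                       several.ok = TRUE)
  structure(list(sparsity_grid = sparsity_grid, metrics = metrics,
                 cv_ddof = cv_ddof, rank_by = match.arg(rank_by)),
            class = "topology_config")
}

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Keeps the `floor(s * E)` strongest edges (by `|z|`, or by signed value
#' with `rank_by = "positive"`), ties broken by upper-triangle index
#' order, as an undirected unweighted adjacency matrix.
#'
#' @param z symmetric connectivity matrix.
#' @param s sparsity fraction in (0, 1).
#' @param rank_by `"absolute"` or `"positive"` edge ranking.
#' @return 0/1 integer adjacency matrix with zero diagonal.
#' @export
binarize_at_sparsity <- function(z, s, rank_by = "absolute") {
  stopifnot(s > 0, s < 1)
  P <- nrow(z)
  ut <- which(upper.tri(z))
  v <- z[ut]
  if (all(v == 0)) warning("all-zero connectivity; edges chosen by tie rule")
  key <- if (rank_by == "positive") v else abs(v)
  ord <- order(-key)  # stable: ties keep index order
  n_keep <- floor(s * length(ut))
  adj <- matrix(0L, P, P)
  keep <- ut[ord[seq_len(n_keep)]]
  adj[keep] <- 1L
  adj + t(adj)
}

#' Nodal efficiency
#'
#' Mean inverse unweighted shortest-path length from a node to all other
#' nodes; unreachable pairs contribute zero.
#'
#' @param adjacency 0/1 symmetric adjacency matrix.
#' @param i node index, or `NULL` (default) for all nodes.
#' @return efficiency in `[0, 1]` (vector if `i` is `NULL`).
#' @export
nodal_efficiency <- function(adjacency, i = NULL) {
  e <- cpp_efficiency(storage_int(adjacency))$nodal
  if (is.null(i)) e else e[i]
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours (the
#' node itself removed): the mean over ordered neighbour pairs of the
#' inverse shortest-path length within the induced subgraph. Nodes with
#' fewer than two neighbours score zero.
#'
#' @inheritParams nodal_efficiency
#' @return efficiency in `[0, 1]` (vector if `i` is `NULL`).
#' @export
local_efficiency <- function(adjacency, i = NULL) {
  e <- cpp_efficiency(storage_int(adjacency))$local
  if (is.null(i)) e else e[i]
}

storage_int <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Trapezoidal area under a metric curve across sparsity levels
#'
#' @param values metric values aligned to `grid`.
#' @param grid sparsity levels.
#' @return trapezoidal integral.
#' @export
auc_over_sparsity <- function(values, grid) {
  if (length(values) != length(grid))
    stop("values and sparsity grid differ in length")
  pracma::trapz(grid, values)
}

#' Coefficient of variation of a temporal series
#'
#' @param series nonempty numeric vector.
#' @param ddof 1 for the sample SD (default), 0 for the population SD.
#' @return `SD / mean`; `NA` with a warning when the mean is not positive.
#' @export
temporal_cv <- function(series, ddof = 1) {
  n <- length(series)
  stopifnot(n >= 1)
  if (ddof == 1 && n < 2) stop("need at least 2 values for the sample SD")
  m <- mean(series)
  if (m <= 0) {
    warning("non-positive mean; CV undefined")
    return(NA_real_)
  }
  s <- sqrt(sum((series - m)^2) / (n - ddof))
  s / m
}

#' Per-window efficiency metrics over the sparsity grid
#'
#' @param z symmetric connectivity matrix of one window.
#' @param cfg a [topology_config()].
#' @return list by metric of `P x n_levels` matrices.
#' @export
window_topology <- function(z, cfg = topology_config()) {
  P <- nrow(z)
  nl <- length(cfg$sparsity_grid)
  out <- lapply(cfg$metrics, function(m) matrix(0, P, nl))
  names(out) <- cfg$metrics
  degenerate <- all(z[upper.tri(z)] == 0)
  if (degenerate)
    warning("all-zero connectivity window; edges chosen by tie rule")
  for (l in seq_len(nl)) {
    adj <- if (degenerate)
      suppressWarnings(binarize_at_sparsity(z, cfg$sparsity_grid[l],
                                            cfg$rank_by))
    else binarize_at_sparsity(z, cfg$sparsity_grid[l], cfg$rank_by)
    eff <- cpp_efficiency(adj)
    if ("nodal_efficiency" %in% cfg$metrics)
      out$nodal_efficiency[, l] <- eff$nodal
    if ("local_efficiency" %in% cfg$metrics)
      out$local_efficiency[, l] <- eff$local
  }
  out
}

#' Temporal variability of graph topology for one subject
#'
#' For every window and sparsity level, binarizes the connectivity matrix
#' and computes per-node efficiency metrics; aggregates each metric across
#' sparsity by the trapezoidal AUC; and summarises each node's AUC series
#' across windows by the coefficient of variation.
#'
#' @param dc a [compute_dynamic_connectome()] result.
#' @param cfg a [topology_config()].
#' @return object of class `topology_variability`: `auc` (list by metric
#'   of `W x P` matrices) and `cv` (tibble `subject_id`, `node`, `metric`,
#'   `cv`).
#' @export
topology_variability <- function(dc, cfg = topology_config()) {
  W <- dim(dc$z_stack)[1]
  P <- dim(dc$z_stack)[2]
  auc <- lapply(cfg$metrics, function(m) matrix(0, W, P))
  names(auc) <- cfg$metrics
  for (w in seq_len(W)) {
    wt <- window_topology(dc$z_stack[w, , ], cfg)
    for (m in cfg$metrics)
      auc[[m]][w, ] <- apply(wt[[m]], 1, auc_over_sparsity,
                             grid = cfg$sparsity_grid)
  }
  cv <- do.call(rbind, lapply(cfg$metrics, function(m)
    tibble::tibble(subject_id = dc$subject_id, node = seq_len(P),
                   metric = m,
                   cv = apply(auc[[m]], 2, function(x)
                     suppressWarnings(temporal_cv(x, cfg$cv_ddof))))))
  structure(list(subject_id = dc$subject_id, auc = auc, cv = cv,
                 config = cfg),
            class = "topology_variability")
}
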