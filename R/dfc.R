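#' Build a tapered sliding-window weight profile
#'
#' Convolves a length-`L` rectangle with a Gaussian kernel evaluated on an
#' integer grid spanning `+/- ceiling(4*sigma)`, keeps the central `L`
#' samples and renormalises them to sum to one. The result is a symmetric,
#' unimodal taper concentrating weight at the window centre.
#'
#' @param L window length in TR units (at least 2).
#' @param sigma Gaussian standard deviation in TR units (default 3).
#' @return object of class `taper_spec` with fields `weights`, `L`,
#'   `sigma`.
#' @export
build_taper <- function(L, sigma = 3) {
  stopifnot(L >= 2, sigma > 0)
  m <- as.integer(ceiling(4 * sigma))
  g <- dnorm(seq(-m, m), sd = sigma)
  if (sum(g) == 0) g[m + 1] <- 1  # degenerate sigma: delta kernel
  full <- convolve_open(rep(1, L), g)
  w <- full[(m + 1):(m + L)]
  w <- w / sum(w)
  structure(list(weights = w, L = as.integer(L), sigma = sigma),
            class = "taper_spec")
}

# full ("open") discrete convolution
convolve_open <- function(x, y) {
  n <- length(x) + length(y) - 1
  out <- numeric(n)
  for (i in seq_along(y)) {
    idx <- seq_along(x) + i - 1
    out[idx] <- out[idx] + x * y[i]
  }
  out
}

#' Number of sliding windows
#'
#' @param T_effective time points available after preprocessing.
#' @param L window length.
#' @param step window step in TR units (default 1).
#' @return `floor((T_effective - L) / step) + 1`.
#' @export
count_windows <- function(T_effective, L, step = 1) {
  if (T_effective < L) stop("fewer time points than the window length")
  as.integer((T_effective - L) %/% step + 1)
}

#' Taper-weighted covariance of a window segment
#'
#' @param segment `P x L` matrix (nodes by window time points).
#' @param weights taper weights summing to one.
#' @return symmetric positive semi-definite `P x P` covariance
#'   `sum_t w_t (x_t - mu_w)(x_t - mu_w)'` about the weighted mean.
#' @export
weighted_covariance <- function(segment, weights) {
  stopifnot(ncol(segment) == length(weights))
  mu <- drop(segment %*% weights)
  Xc <- segment - mu
  S <- tcrossprod(Xc * rep(weights, each = nrow(segment)), Xc)
  S <- (S + t(S)) / 2
  if (any(diag(S) <= 0))
    stop("zero-variance node in window (nodes: ",
         paste(which(diag(S) <= 0), collapse = ", "), ")")
  S
}

#' Sparse precision matrix by graphical lasso
#'
#' Maximises `log det(Theta) - tr(S Theta) - lambda * sum_{i != j}
#' |Theta_ij|` over positive-definite matrices by block coordinate descent.
#' Fails explicitly on non-convergence.
#'
#' @param S symmetric covariance matrix.
#' @param lambda nonnegative L1 penalty on off-diagonal precision entries.
#' @param tol convergence tolerance on the working covariance (maximum
#'   entry change).
#' @param maxit maximum outer iterations.
#' @return symmetric positive-definite precision matrix.
#' @export
glasso_precision <- function(S, lambda, tol = 1e-7, maxit = 1000) {
  stopifnot(lambda >= 0)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("S must be symmetric")
  cpp_glasso(as.matrix(S), lambda, tol, maxit)
}

#' Window estimator configuration
#'
#' @param step window step in TR (default 1).
#' @param lambda_grid candidate L1 penalties, ascending (default 10 values
#'   log-spaced on 0.03-1).
#' @param cv_folds contiguous-block cross-validation folds (default 5).
#' @param lambda fixed penalty; `NULL` (default) selects per subject by
#'   cross-validation.
#' @return object of class `window_config`.
#' @export
window_config <- function(step = 1,
                          lambda_grid = exp(seq(log(0.03), log(1),
                                                length.out = 10)),
                          cv_folds = 5, lambda = NULL) {
  stopifnot(step >= 1, length(lambda_grid) >= 1, all(lambda_grid > 0),
            !is.unsorted(lambda_grid), cv_folds >= 2)
  structure(list(step = as.integer(step), lambda_grid = lambda_grid,
                 cv_folds = as.integer(cv_folds), lambda = lambda),
            class = "window_config")
}

#' Select the graphical-lasso penalty by cross-validation
#'
#' Splits the subject's full (unwindowed) time series into contiguous
#' blocks; for each candidate penalty, fits the precision on the training
#' covariance and scores the held-out Gaussian log-likelihood
#' `log det(Theta) - tr(S_test Theta)`. Returns the penalty with the best
#' mean held-out score (ties go to the smaller penalty).
#'
#' @param ts a [subject_ts()].
#' @param grid candidate penalties.
#' @param folds number of contiguous folds.
#' @return selected penalty, with the score curve in the `scores`
#'   attribute.
#' @export
select_lambda <- function(ts, grid = window_config()$lambda_grid,
                          folds = 5) {
  T <- ncol(ts$data)
  if (T < folds) stop("fewer time points than folds")
  bounds <- floor(seq(0, T, length.out = folds + 1))
  scores <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    test_idx <- (bounds[f] + 1):bounds[f + 1]
    S_train <- sample_cov(ts$data[, -test_idx, drop = FALSE])
    S_test <- sample_cov(ts$data[, test_idx, drop = FALSE])
    for (g in seq_along(grid)) {
      Theta <- glasso_precision(S_train, grid[g])
      scores[f, g] <- determinant_ll(Theta, S_test)
    }
  }
  mean_scores <- colMeans(scores)
  lambda <- grid[which.max(mean_scores)]
  attr(lambda, "scores") <- mean_scores
  lambda
}

sample_cov <- function(X) {
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / ncol(X)
  (S + t(S)) / 2
}

determinant_ll <- function(Theta, S) {
  as.numeric(determinant(Theta, logarithm = TRUE)$modulus) -
    sum(S * Theta)
}

#' Convert a precision matrix to Fisher-z connectivity
#'
#' Inverts the precision to a covariance, normalises to correlations,
#' clips `|r|` at `1 - 1e-7` and applies the Fisher r-to-z transform.
#' The diagonal is set to zero.
#'
#' @param Theta symmetric positive-definite precision matrix.
#' @return symmetric z-score matrix with zero diagonal.
#' @export
precision_to_z <- function(Theta) {
  C <- tryCatch(solve(Theta), error = function(e)
    stop("precision matrix is not invertible"))
  if (any(diag(C) <= 0)) stop("precision matrix is not positive definite")
  r <- cov2cor((C + t(C)) / 2)
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  (z + t(z)) / 2
}

#' Compute a subject's dynamic connectome
#'
#' Slides a tapered window along the cleaned time series; in each window
#' estimates the taper-weighted covariance, the graphical-lasso precision
#' at the subject's penalty, and the Fisher-z connectivity matrix.
#'
#' @param ts a [subject_ts()] (already preprocessed).
#' @param taper a [build_taper()] spec.
#' @param cfg a [window_config()]; if `cfg$lambda` is `NULL` the penalty is
#'   selected per subject by [select_lambda()].
#' @return object of class `dynamic_connectome` with the `W x P x P`
#'   z-stack, window start indices and the penalty used.
#' @export
compute_dynamic_connectome <- function(ts, taper, cfg = window_config()) {
  P <- nrow(ts$data)
  T <- ncol(ts$data)
  L <- taper$L
  if (T < L) stop("time series shorter than the window")
  lambda <- cfg$lambda
  if (is.null(lambda))
    lambda <- as.numeric(select_lambda(ts, cfg$lambda_grid, cfg$cv_folds))
  starts <- seq(1L, T - L + 1L, by = cfg$step)
  z <- array(0, c(length(starts), P, P))
  for (w in seq_along(starts)) {
    seg <- ts$data[, starts[w]:(starts[w] + L - 1), drop = FALSE]
    S <- weighted_covariance(seg, taper$weights)
    Theta <- glasso_precision(S, lambda)
    z[w, , ] <- precision_to_z(Theta)
  }
  structure(list(subject_id = ts$subject_id, z_stack = z,
                 window_starts = starts, L = L, sigma = taper$sigma,
                 lambda = lambda, tr_seconds = ts$tr_seconds,
                 step = cfg$step),
            class = "dynamic_connectome")
}

#' @export
print.dynamic_connectome <- function(x, ...) {
  cat(sprintf(
    "<dynamic_connectome %s: %d windows x %d x %d (L = %d, lambda = %.4g)>\n",
    x$subject_id, dim(x$z_stack)[1], dim(x$z_stack)[2], dim(x$z_stack)[3],
    x$L, x$lambda))
  invisible(x)
}

#' Upper-triangle window vectors of a dynamic connectome
#'
#' @param dc a [compute_dynamic_connectome()] result.
#' @return `W x P(P-1)/2` matrix; edges in column-major upper-triangle
#'   order, the edge order used throughout clustering and ranking.
#' @export
connectome_vectors <- function(dc) {
  P <- dim(dc$z_stack)[2]
  ut <- upper.tri(matrix(0, P, P))
  t(apply(dc$z_stack, 1, function(m) m[ut]))
}
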