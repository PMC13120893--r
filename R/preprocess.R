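#' Preprocessing configuration
#'
#' Post-ICA time-series cleaning parameters: initial-frame removal,
#' polynomial detrending, despiking and zero-phase low-pass filtering.
#'
#' @param n_drop initial time points removed (default 10).
#' @param detrend_order highest polynomial order regressed out (default 3:
#'   linear, quadratic and cubic trends plus intercept).
#' @param despike_c1 MAD-scaled residual threshold above which samples are
#'   compressed (default 2.5).
#' @param despike_c2 saturation bound of the compression map (default 4).
#' @param lowpass_hz low-pass cutoff in Hz (default 0.15).
#' @param filter_order Butterworth order (default 5), applied
#'   forward-backward for zero phase.
#' @param standardize scale each node to unit variance after filtering
#'   (default `TRUE`). Filtering shrinks the variance scale, and the
#'   graphical-lasso penalty acts on the covariance scale, so
#'   variance-normalised series keep one penalty grid meaningful across
#'   subjects and preprocessing choices.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_drop = 10, detrend_order = 3,
                              despike_c1 = 2.5, despike_c2 = 4,
                              lowpass_hz = 0.15, filter_order = 5,
                              standardize = TRUE) {
  stopifnot(n_drop >= 0, detrend_order >= 0, despike_c1 > 0,
            despike_c2 > despike_c1, lowpass_hz > 0, filter_order >= 1)
  structure(list(n_drop = as.integer(n_drop),
                 detrend_order = as.integer(detrend_order),
                 despike_c1 = despike_c1, despike_c2 = despike_c2,
                 lowpass_hz = lowpass_hz,
                 filter_order = as.integer(filter_order),
                 standardize = isTRUE(standardize)),
            class = "preprocess_config")
}

#' Remove initial time points
#'
#' @param ts a [subject_ts()].
#' @param n_drop number of leading time points to discard.
#' @return the shortened [subject_ts()].
#' @export
drop_initial <- function(ts, n_drop) {
  T <- ncol(ts$data)
  if (n_drop >= T) stop("n_drop must be smaller than the number of time points")
  if (n_drop == 0) return(ts)
  subject_ts(ts$subject_id, ts$data[, -seq_len(n_drop), drop = FALSE],
             ts$tr_seconds)
}

# orthonormal polynomial design matrix (intercept + orders 1..order)
poly_design <- function(n, order) {
  if (order == 0) return(matrix(1 / sqrt(n), n, 1))
  cbind(1 / sqrt(n), stats::poly(seq_len(n), degree = order))
}

#' Polynomial detrending
#'
#' Projects the series onto the orthogonal complement of the polynomial
#' subspace of degree `0..order` in the time index (one joint least-squares
#' projection, not sequential regression).
#'
#' @param series numeric vector.
#' @param order highest polynomial order (default 3).
#' @return residual series with (numerically) zero mean.
#' @export
detrend_poly <- function(series, order = 3) {
  n <- length(series)
  if (n <= order + 1) stop("series too short for polynomial order ", order)
  X <- poly_design(n, order)
  drop(series - X %*% crossprod(X, series))
}

#' Despike a series by saturating compression of MAD-outliers
#'
#' Residuals from a least-squares cubic baseline are scaled by the MAD
#' estimate of their dispersion; samples beyond `c1` scaled units are
#' compressed toward the baseline with a tanh map saturating at `c2` units,
#' so no output residual exceeds `c2 * sigma_MAD`. Sub-threshold samples
#' are untouched.
#'
#' @param series numeric vector.
#' @param c1 compression onset threshold in MAD-scaled units.
#' @param c2 saturation bound (`c2 > c1`).
#' @param baseline_order polynomial order of the baseline fit (default 3).
#' @return despiked series.
#' @export
despike <- function(series, c1 = 2.5, c2 = 4, baseline_order = 3) {
  stopifnot(length(series) > 0, c2 > c1, c1 > 0)
  if (length(series) <= baseline_order + 1) return(series)
  resid <- detrend_poly(series, baseline_order)
  baseline <- series - resid
  sigma <- mad(resid)
  if (sigma == 0) {
    warning("zero MAD; series returned unchanged")
    return(series)
  }
  s <- resid / sigma
  hot <- abs(s) > c1
  s[hot] <- sign(s[hot]) *
    (c1 + (c2 - c1) * tanh((abs(s[hot]) - c1) / (c2 - c1)))
  baseline + s * sigma
}

#' Zero-phase low-pass filtering
#'
#' Butterworth low-pass applied forward and backward (no group delay), with
#' odd-symmetric edge padding long enough for the filter transient to decay
#' before the retained segment.
#'
#' @param series numeric vector.
#' @param lowpass_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * tr_seconds)`.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param filter_order Butterworth order (default 5).
#' @return filtered series of the same length.
#' @export
lowpass <- function(series, lowpass_hz = 0.15, tr_seconds = 0.72,
                    filter_order = 5) {
  nyquist <- 1 / (2 * tr_seconds)
  if (lowpass_hz >= nyquist)
    stop("cutoff (", lowpass_hz, " Hz) must be below Nyquist (", nyquist,
         " Hz)")
  w <- lowpass_hz / nyquist
  bf <- signal::butter(filter_order, w)
  n <- length(series)
  np <- min(n - 1L, max(3L * (2L * filter_order + 1L),
                        as.integer(ceiling(30 / w))))
  left <- 2 * series[1] - series[(np + 1):2]
  right <- 2 * series[n] - series[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(left, series, right))
  y[(np + 1):(np + n)]
}

#' Full time-series preprocessing chain
#'
#' Initial-frame removal, then per node: polynomial detrending, despiking,
#' zero-phase low-pass filtering and (by default) variance normalisation.
#'
#' @param ts a [subject_ts()].
#' @param cfg a [preprocess_config()].
#' @return cleaned [subject_ts()] with the applied parameters attached as
#'   the `preprocess` attribute.
#' @export
preprocess_timeseries <- function(ts, cfg = preprocess_config()) {
  out <- drop_initial(ts, cfg$n_drop)
  dat <- out$data
  for (i in seq_len(nrow(dat))) {
    x <- detrend_poly(dat[i, ], cfg$detrend_order)
    x <- despike(x, cfg$despike_c1, cfg$despike_c2, cfg$detrend_order)
    x <- lowpass(x, cfg$lowpass_hz, out$tr_seconds, cfg$filter_order)
    if (isTRUE(cfg$standardize)) {
      s <- sd(x)
      if (s == 0) stop("zero-variance node ", i, " after filtering")
      x <- x / s
    }
    dat[i, ] <- x
  }
  out$data <- dat
  attr(out, "preprocess") <- unclass(cfg)
  out
}
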