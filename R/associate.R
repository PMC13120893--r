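#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualises `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals. The two-sided p-value uses
#' `t = r * sqrt((n - 2 - q) / (1 - r^2))` on `n - 2 - q` degrees of
#' freedom, `q` the number of covariates. Incomplete cases are dropped
#' pairwise.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (or vector) of covariates, rows
#'   aligned with `x`/`y`; `NULL` gives the unadjusted correlation.
#' @return list with `r`, `p`, `n`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  ok <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(0, length(x))
                              else covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= q + 2) stop("too few complete cases (n = ", n, ")")
  X <- cbind(1, if (q) covariates[ok, , drop = FALSE])
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant residuals; partial correlation undefined")
  r <- cor(rx, ry)
  df <- n - 2 - q
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment within one family of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

covariate_matrix <- function(cohort) {
  cbind(age = cohort$age,
        gender = as.numeric(cohort$gender == "male"))
}

#' Associate state temporal metrics with the BMI covariate
#'
#' One age/gender-adjusted partial Pearson test per (state, FW) and
#' (state, MDT) pair against BMI. With `family = "joint"` (default) all
#' `2k` tests form one FDR family; `"separate"` corrects FW and MDT as two
#' families of `k`. NT is tested once, uncorrected. Subjects lacking MDT
#' for a state (never visited) are dropped pairwise for that test only.
#'
#' @param metrics result of [state_metrics()].
#' @param cohort cohort tibble with `subject_id`, `bmi`, `age`, `gender`.
#' @param family `"joint"` or `"separate"` FDR grouping of FW/MDT tests.
#' @param min_n minimum complete cases per test (default 10).
#' @return tibble `family`, `state`, `metric`, `r`, `p_raw`, `p_corr`,
#'   `n`.
#' @export
associate_state_metrics <- function(metrics, cohort,
                                    family = c("joint", "separate"),
                                    min_n = 10) {
  family <- match.arg(family)
  by_state <- merge(metrics$by_state, cohort, by = "subject_id")
  k <- max(by_state$state)
  rows <- list()
  for (s in seq_len(k)) for (met in c("fw", "mdt")) {
    d <- by_state[by_state$state == s, ]
    ok <- stats::complete.cases(d[[met]], d$bmi, d$age, d$gender)
    if (sum(ok) < min_n) {
      warning("state ", s, " ", toupper(met), ": only ", sum(ok),
              " complete cases; test skipped")
      next
    }
    pp <- partial_pearson(d[[met]], d$bmi, covariate_matrix(d))
    rows[[length(rows) + 1]] <- tibble::tibble(
      family = if (family == "joint") "fw_mdt" else met,
      state = s, metric = toupper(met), r = pp$r, p_raw = pp$p, n = pp$n)
  }
  if (!length(rows))
    stop("no state-metric test had at least min_n complete cases")
  out <- do.call(rbind, rows)
  out$p_corr <- NA_real_
  for (fam in unique(out$family))
    out$p_corr[out$family == fam] <- fdr_adjust(out$p_raw[out$family == fam])

  nt <- merge(metrics$by_subject, cohort, by = "subject_id")
  pp <- partial_pearson(nt$nt, nt$bmi, covariate_matrix(nt))
  out <- rbind(out, tibble::tibble(family = "nt", state = NA_integer_,
                                   metric = "NT", r = pp$r, p_raw = pp$p,
                                   n = pp$n, p_corr = pp$p))
  tibble::as_tibble(out[, c("family", "state", "metric", "r", "p_raw",
                            "p_corr", "n")])
}

#' Associate topology temporal variability with the BMI covariate
#'
#' One age/gender-adjusted partial Pearson test per (node, metric) between
#' the node's CV and BMI; FDR correction is applied per metric family
#' across nodes. Degenerate (constant or undefined) CV columns are
#' excluded and reported.
#'
#' @param tv_list list of [topology_variability()] results (one per
#'   subject).
#' @param cohort cohort tibble.
#' @return tibble `family`, `node`, `metric`, `r`, `p_raw`, `p_corr`,
#'   `n`, plus an `excluded` attribute naming dropped columns.
#' @export
associate_topology <- function(tv_list, cohort) {
  cv <- do.call(rbind, lapply(tv_list, `[[`, "cv"))
  cv <- merge(cv, cohort, by = "subject_id")
  rows <- list(); excluded <- character(0)
  for (met in unique(cv$metric)) for (nd in sort(unique(cv$node))) {
    d <- cv[cv$metric == met & cv$node == nd, ]
    if (all(is.na(d$cv)) || sd(d$cv, na.rm = TRUE) == 0) {
      excluded <- c(excluded, paste0(met, ":node", nd))
      next
    }
    pp <- partial_pearson(d$cv, d$bmi, covariate_matrix(d))
    rows[[length(rows) + 1]] <- tibble::tibble(
      family = met, node = nd, metric = met, r = pp$r, p_raw = pp$p,
      n = pp$n)
  }
  out <- do.call(rbind, rows)
  out$p_corr <- NA_real_
  for (fam in unique(out$family))
    out$p_corr[out$family == fam] <- fdr_adjust(out$p_raw[out$family == fam])
  out <- tibble::as_tibble(out[, c("family", "node", "metric", "r",
                                   "p_raw", "p_corr", "n")])
  if (length(excluded))
    message("excluded degenerate CV columns: ",
            paste(excluded, collapse = ", "))
  attr(out, "excluded") <- excluded
  out
}

#' BMI-group contrasts on state temporal metrics
#'
#' Welch two-sample t-tests of FW and MDT per state for healthy-weight vs
#' overweight and healthy-weight vs obese subjects (underweight subjects
#' are not part of the three-group contrasts). Negative `t` means the
#' healthy-weight group mean is lower. One FDR family across all
#' contrasts.
#'
#' @param metrics result of [state_metrics()].
#' @param cohort cohort tibble.
#' @param min_n minimum subjects per group (default 2).
#' @return tibble `contrast`, `state`, `metric`, `t`, `p_raw`, `p_corr`,
#'   `n_healthy`, `n_comparison`.
#' @export
group_contrasts <- function(metrics, cohort, min_n = 2) {
  d <- merge(metrics$by_state, cohort, by = "subject_id")
  d$group <- assign_bmi_group(d$bmi)
  k <- max(d$state)
  rows <- list()
  for (comp in c("overweight", "obese")) for (s in seq_len(k))
    for (met in c("fw", "mdt")) {
      h <- d[[met]][d$group == "healthy" & d$state == s]
      o <- d[[met]][d$group == comp & d$state == s]
      h <- h[!is.na(h)]; o <- o[!is.na(o)]
      if (length(h) < min_n || length(o) < min_n) {
        warning("undersized group for healthy vs ", comp, ", state ", s)
        next
      }
      tt <- stats::t.test(h, o)
      rows[[length(rows) + 1]] <- tibble::tibble(
        contrast = paste0("healthy_vs_", comp), state = s,
        metric = toupper(met), t = unname(tt$statistic),
        p_raw = tt$p.value, n_healthy = length(h),
        n_comparison = length(o))
    }
  out <- do.call(rbind, rows)
  out$p_corr <- fdr_adjust(out$p_raw)
  tibble::as_tibble(out[, c("contrast", "state", "metric", "t", "p_raw",
                            "p_corr", "n_healthy", "n_comparison")])
}
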