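#' Run the dynamic-connectivity stage for a list of subjects
#'
#' Optional preprocessing followed by per-subject dynamic connectome
#' estimation with a shared taper and window configuration.
#'
#' @param subjects list of [subject_ts()] objects.
#' @param preprocess a [preprocess_config()], or `NULL` to skip cleaning.
#' @param L,sigma taper parameters (window length in TR, Gaussian SD in
#'   TR).
#' @param window a [window_config()].
#' @param verbose print per-subject progress.
#' @return list of [compute_dynamic_connectome()] results.
#' @export
run_dfc <- function(subjects, preprocess = preprocess_config(),
                    L = 70, sigma = 3, window = window_config(),
                    verbose = FALSE) {
  taper <- build_taper(L, sigma)
  lapply(seq_along(subjects), function(i) {
    ts <- subjects[[i]]
    if (!is.null(preprocess)) ts <- preprocess_timeseries(ts, preprocess)
    dc <- compute_dynamic_connectome(ts, taper, window)
    if (verbose)
      message(sprintf("dfc %s: %d windows, lambda = %.4g", dc$subject_id,
                      length(dc$window_starts), dc$lambda))
    dc
  })
}

#' End-to-end state analysis of a cohort
#'
#' Dynamic connectome estimation, state identification (elbow-selected or
#' fixed `k`), temporal metrics, and covariate-adjusted association tests
#' against BMI.
#'
#' @param subjects list of [subject_ts()] objects.
#' @param cohort cohort tibble with `subject_id`, `bmi`, `age`, `gender`.
#' @param preprocess,L,sigma,window forwarded to [run_dfc()].
#' @param k_range,k,n_replicates,scan_replicates,seed forwarded to
#'   [identify_states()].
#' @param verbose print stage progress.
#' @return list with `dc_list`, `model`, `metrics`, `associations`.
#' @export
run_state_pipeline <- function(subjects, cohort,
                               preprocess = preprocess_config(),
                               L = 70, sigma = 3,
                               window = window_config(),
                               k_range = 2:10, k = NULL,
                               n_replicates = 100,
                               scan_replicates = n_replicates,
                               seed = 1, verbose = FALSE) {
  dc_list <- run_dfc(subjects, preprocess, L, sigma, window, verbose)
  model <- identify_states(dc_list, k_range = k_range, k = k,
                           n_replicates = n_replicates,
                           scan_replicates = scan_replicates, seed = seed)
  metrics <- state_metrics(model)
  associations <- associate_state_metrics(metrics, cohort)
  list(dc_list = dc_list, model = model, metrics = metrics,
       associations = associations)
}
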