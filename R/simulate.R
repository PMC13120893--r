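#' Default block-structured state covariance matrices
#'
#' Builds `K = 4` correlation-scale covariance matrices over three node
#' blocks that stand in for canonical resting-state networks: a "visual"
#' block (first ~30% of nodes), a "sensorimotor" block (next ~30%) and an
#' "association" block (the rest). Each state has a distinct within/between
#' block correlation profile; the third state is visual-dominant, with
#' strong positive intra-visual and visual-sensorimotor correlation and
#' negative visual-association correlation, so that prolonged dwelling in it
#' suppresses the temporal variability of visual-node graph metrics.
#'
#' @param n_nodes number of nodes (at least 6).
#' @return list of four symmetric positive-definite matrices with unit
#'   diagonal.
#' @export
default_state_covariances <- function(n_nodes = 10) {
  stopifnot(n_nodes >= 6)
  b1 <- seq_len(max(2, round(0.3 * n_nodes)))                    # visual
  b2 <- seq(max(b1) + 1, max(b1) + max(2, round(0.3 * n_nodes))) # sensorimotor
  b3 <- seq(max(b2) + 1, n_nodes)                                # association

  blockfill <- function(rho_spec) {
    S <- diag(n_nodes)
    for (sp in rho_spec) {
      S[sp$rows, sp$cols] <- sp$rho
      S[sp$cols, sp$rows] <- sp$rho
    }
    diag(S) <- 1
    # large blocks with inter-block coupling can lose definiteness; shrink
    # uniformly toward the identity (pattern-preserving) when needed
    lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 0.02) S <- cov2cor(S + diag(0.02 - lmin, n_nodes))
    S
  }
  states <- list(
    # state 1: sensorimotor-dominant with sensorimotor-association coupling
    blockfill(list(list(rows = b2, cols = b2, rho = 0.65),
                   list(rows = b2, cols = b3, rho = 0.35))),
    # state 2: weak association-only connectivity (weakest overall)
    blockfill(list(list(rows = b3, cols = b3, rho = 0.40))),
    # state 3: visual-dominant (the coupling target)
    blockfill(list(list(rows = b1, cols = b1, rho = 0.70),
                   list(rows = b1, cols = b2, rho = 0.40),
                   list(rows = b1, cols = b3, rho = -0.25))),
    # state 4: anticorrelated sensorimotor/association configuration
    blockfill(list(list(rows = b2, cols = b2, rho = 0.50),
                   list(rows = b3, cols = b3, rho = 0.55),
                   list(rows = b2, cols = b3, rho = -0.25)))
  )
  for (S in states) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("default state covariance is not positive definite")
  }
  states
}

#' Simulation configuration for a Markov-switching covariance cohort
#'
#' Each subject's multivariate time series is generated from `K` latent
#' covariance states following a first-order Markov chain. The
#' self-transition probability of `target_state` is modulated on the
#' log-odds scale by the subject's BMI-like covariate, so that higher
#' covariate values prolong dwelling in that state; the remaining row mass
#' is renormalised proportionally.
#'
#' @param n_subjects,n_nodes,n_timepoints,n_states cohort dimensions.
#' @param state_covariances list of `n_states` symmetric positive-definite
#'   matrices; defaults to [default_state_covariances()].
#' @param base_transition row-stochastic `K x K` matrix at the covariate
#'   mean; default self-transition 0.995 with the remainder spread
#'   evenly.
#' @param covariate_mean,covariate_sd,covariate_range BMI-like covariate:
#'   truncated normal within `covariate_range` (kg/m^2 scale).
#' @param dwell_coupling log-odds increment to the target state's
#'   self-transition probability per covariate unit.
#' @param target_state state whose dwelling is covariate-coupled; default
#'   state 3 (or the last state when fewer exist).
#' @param age_range,gender_proportion demographics; `gender_proportion` is
#'   the proportion of males.
#' @param noise_sd standard deviation of additive isotropic observation
#'   noise.
#' @param ar_coef optional AR(1) coefficient for temporally correlated
#'   innovations (0 = white, the default).
#' @param initial_state fixed initial state for every subject, or `NULL`
#'   to draw uniformly.
#' @param tr_seconds repetition time attached to simulated subjects.
#' @param seed RNG seed; simulation is deterministic given the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 60, n_nodes = 10, n_timepoints = 800,
                       n_states = 4, state_covariances = NULL,
                       base_transition = NULL,
                       covariate_mean = 26.5, covariate_sd = 5,
                       covariate_range = c(16, 46),
                       dwell_coupling = 0.15, target_state = NULL,
                       age_range = c(22, 37), gender_proportion = 0.52,
                       noise_sd = 0.2, ar_coef = 0, initial_state = NULL,
                       tr_seconds = 0.72, seed = 1) {
  if (is.null(state_covariances)) {
    state_covariances <- default_state_covariances(n_nodes)[seq_len(n_states)]
    if (n_states > 4)
      stop("default state covariances cover at most 4 states; supply your own")
  }
  if (is.null(base_transition)) {
    p_self <- 0.995
    base_transition <- matrix((1 - p_self) / (n_states - 1),
                              n_states, n_states)
    diag(base_transition) <- p_self
    if (n_states == 1) base_transition <- matrix(1, 1, 1)
  }
  if (is.null(target_state)) target_state <- min(3, n_states)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints), n_states = as.integer(n_states),
    state_covariances = state_covariances,
    base_transition = base_transition,
    covariate_mean = covariate_mean, covariate_sd = covariate_sd,
    covariate_range = covariate_range,
    dwell_coupling = dwell_coupling, target_state = as.integer(target_state),
    age_range = age_range, gender_proportion = gender_proportion,
    noise_sd = noise_sd, ar_coef = ar_coef, initial_state = initial_state,
    tr_seconds = tr_seconds, seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_nodes >= 1, cfg$n_timepoints >= 1,
            cfg$n_states >= 1, cfg$noise_sd >= 0)
  if (cfg$gender_proportion < 0 || cfg$gender_proportion > 1)
    stop("gender_proportion must lie in [0, 1]")
  if (length(cfg$state_covariances) != cfg$n_states)
    stop("need one covariance matrix per state")
  for (s in seq_len(cfg$n_states)) {
    S <- cfg$state_covariances[[s]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
      stop("state covariance ", s, " is not symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("state covariance ", s, " is not positive definite")
  }
  P <- cfg$base_transition
  if (nrow(P) != cfg$n_states || ncol(P) != cfg$n_states)
    stop("base_transition must be K x K")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("base_transition rows must be nonnegative and sum to 1")
  if (cfg$target_state < 1 || cfg$target_state > cfg$n_states)
    stop("target_state out of range")
  invisible(cfg)
}

# covariate-modulated transition matrix for one subject
subject_transition <- function(cfg, covariate) {
  P <- cfg$base_transition
  tgt <- cfg$target_state
  p0 <- P[tgt, tgt]
  if (1 - p0 < .Machine$double.eps) return(P)  # absorbing row: nothing to move
  p_self <- plogis(qlogis(p0) +
                     cfg$dwell_coupling * (covariate - cfg$covariate_mean))
  row <- P[tgt, ] * (1 - p_self) / (1 - p0)
  row[tgt] <- p_self
  if (any(row < -1e-12) || any(row > 1 + 1e-12))
    stop("renormalised transition row leaves [0, 1]")
  P[tgt, ] <- pmin(pmax(row, 0), 1)
  P
}

simulate_chain <- function(P, T, initial_state = NULL) {
  K <- nrow(P)
  s <- integer(T)
  s[1] <- if (is.null(initial_state)) sample.int(K, 1) else initial_state
  if (T > 1)
    for (t in 2:T) s[t] <- sample.int(K, 1, prob = P[s[t - 1], ])
  s
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Simulate latent state sequences and covariates only
#'
#' Lightweight companion to [simulate_cohort()] that draws the cohort table
#' and per-subject latent Markov chains without generating observations.
#' Useful for calibration studies (e.g. null simulations of the
#' state-metric association tests) where the observation model is not
#' needed.
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (tibble), `states` (`n_subjects x T` integer
#'   matrix) and `p_self` (realised target-state self-transition
#'   probabilities).
#' @export
simulate_state_sequences <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  bmi <- rtruncnorm1(n, cfg$covariate_mean, cfg$covariate_sd,
                     cfg$covariate_range[1], cfg$covariate_range[2])
  age <- sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE)
  gender <- ifelse(rbinom(n, 1, cfg$gender_proportion) == 1, "male", "female")
  cohort <- tibble::tibble(
    subject_id = sprintf("sub%03d", seq_len(n)),
    bmi = bmi, age = as.numeric(age), gender = gender)

  states <- matrix(0L, n, cfg$n_timepoints)
  p_self <- numeric(n)
  for (i in seq_len(n)) {
    P <- subject_transition(cfg, bmi[i])
    p_self[i] <- P[cfg$target_state, cfg$target_state]
    states[i, ] <- simulate_chain(P, cfg$n_timepoints, cfg$initial_state)
  }
  list(cohort = cohort, states = states, p_self = p_self)
}

#' Simulate a synthetic cohort from Markov-switching covariance states
#'
#' Draws a BMI-like covariate, demographics and a latent `K`-state Markov
#' chain per subject (with the target state's self-transition probability
#' coupled to the covariate on the log-odds scale), then generates Gaussian
#' observations from the current state's covariance plus isotropic noise.
#'
#' @param cfg a [sim_config()].
#' @return list with `subjects` (list of [subject_ts()] objects) and
#'   `truth` (cohort table, latent state matrix, realised self-transition
#'   probabilities, and the generating configuration).
#' @export
simulate_cohort <- function(cfg) {
  seqs <- simulate_state_sequences(cfg)
  P <- cfg$n_nodes
  T <- cfg$n_timepoints
  chol_list <- lapply(cfg$state_covariances, function(S)
    chol(S + diag(cfg$noise_sd^2, P)))

  subjects <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    Z <- matrix(rnorm(P * T), P, T)
    if (cfg$ar_coef > 0) {
      a <- cfg$ar_coef
      for (t in 2:T) Z[, t] <- a * Z[, t - 1] + sqrt(1 - a^2) * Z[, t]
    }
    X <- matrix(0, P, T)
    st <- seqs$states[i, ]
    for (s in seq_len(cfg$n_states)) {
      idx <- which(st == s)
      if (length(idx))
        X[, idx] <- crossprod(chol_list[[s]], Z[, idx, drop = FALSE])
    }
    subjects[[i]] <- subject_ts(seqs$cohort$subject_id[i], X,
                                tr_seconds = cfg$tr_seconds)
  }
  list(subjects = subjects,
       truth = list(cohort = seqs$cohort, states = seqs$states,
                    p_self = seqs$p_self, config = cfg))
}

#' Fisher-z connectivity pattern of a planted state
#'
#' Upper-triangle Fisher-z transform of the correlation matrix implied by a
#' state covariance (observation noise included), the reference pattern
#' against which recovered centroids are matched.
#'
#' @param cfg a [sim_config()].
#' @param state state index.
#' @return numeric vector of length `P(P-1)/2`.
#' @export
planted_state_pattern <- function(cfg, state) {
  S <- cfg$state_covariances[[state]] +
    diag(cfg$noise_sd^2, cfg$n_nodes)
  r <- cov2cor(S)
  atanh(pmin(pmax(r[upper.tri(r)], -1 + 1e-7), 1 - 1e-7))
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Writes one tab-delimited time-series file per subject (rows = time
#' points, columns = nodes), the cohort CSV, the ground truth as JSON, and
#' a manifest listing every file together with the generating seed.
#'
#' @param dir output directory (created if needed).
#' @param sim result of [simulate_cohort()].
#' @return the manifest, invisibly a list written to `manifest.json`.
#' @export
write_fixture <- function(dir, sim) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts_files <- character(length(sim$subjects))
  for (i in seq_along(sim$subjects)) {
    f <- file.path(dir, paste0(sim$subjects[[i]]$subject_id, ".tsv"))
    write_matrix(f, t(sim$subjects[[i]]$data))
    ts_files[i] <- basename(f)
  }
  cohort_file <- file.path(dir, "cohort.csv")
  utils::write.csv(sim$truth$cohort, cohort_file, row.names = FALSE)
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(states = sim$truth$states, p_self = sim$truth$p_self,
         target_state = sim$truth$config$target_state,
         dwell_coupling = sim$truth$config$dwell_coupling),
    truth_file, digits = NA)
  manifest <- list(seed = sim$truth$config$seed,
                   tr_seconds = sim$truth$config$tr_seconds,
                   timeseries = ts_files,
                   cohort = basename(cohort_file),
                   truth = basename(truth_file))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
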