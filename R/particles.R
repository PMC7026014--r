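#' @useDynLib tsmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma rbeta rexp dnorm dbeta dgamma dlnorm
#'   optimize quantile sd setNames weighted.mean
NULL

## Numerically stable log(sum(exp(x))). Tolerates -Inf entries; returns -Inf
## for an all--Inf vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Normalise log-weights to probabilities summing to one.
normalise_log_weights <- function(lw) {
  if (all(!is.finite(lw))) stop("invalid weights: all particles have zero weight")
  if (anyNA(lw)) stop("invalid weights: NaN log-weights")
  exp(lw - logsumexp(lw))
}

#' Create a particle system
#'
#' A particle system is the state of a running SMC sampler: `P` model-specific
#' particle values, unnormalised log-weights, the index of the model currently
#' targeted, the annealing fraction within the current bridge, and the
#' accumulated log-evidence increments (one per completed reweighting step).
#'
#' @param values particle values. Any container the bridges in use understand:
#'   a numeric vector, a list of states, or an application-specific population
#'   object with a `select` method on its bridge.
#' @param n_particles number of particles `P`.
#' @param log_weights unnormalised log-weights (default: uniform).
#' @param model_index integer model index `t`.
#' @param log_z0 log normalising constant of the initial distribution
#'   (0 for a normalised initial density).
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(values, n_particles,
                            log_weights = rep(0, n_particles),
                            model_index = 1L, log_z0 = 0) {
  stopifnot(n_particles >= 1, length(log_weights) == n_particles)
  structure(list(values = values,
                 log_weights = log_weights,
                 n_particles = as.integer(n_particles),
                 model_index = as.integer(model_index),
                 anneal_fraction = 0,
                 log_z0 = log_z0,
                 log_evidence_increments = numeric(0)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system: P=%d, model t=%d, gamma=%.4f, logZ=%.4f, ESS=%.1f>\n",
              x$n_particles, x$model_index, x$anneal_fraction,
              log_evidence(x), ess(normalise_log_weights(x$log_weights))))
  invisible(x)
}

#' Effective sample size of a normalised weight vector
#'
#' `ESS = 1 / sum(w^2)`, between 1 (a single atom) and `P` (uniform weights).
#'
#' @param normalized_weights non-negative weights summing to one.
#' @return the effective sample size.
#' @export
ess <- function(normalized_weights) {
  w <- normalized_weights
  if (anyNA(w) || any(w < 0) || sum(w) == 0)
    stop("invalid weights: must be non-negative and not all zero")
  1 / sum(w^2)
}

#' Conditional effective sample size (CESS)
#'
#' Measures the discrepancy a single incremental reweight introduces:
#' `CESS = P * (sum(w * omega))^2 / sum(w * omega^2)` where `w` are the current
#' normalised weights and `omega` the incremental weights. Equals `P` when the
#' increments are constant across particles.
#'
#' @param normalized_weights current normalised weights.
#' @param incremental_weights non-negative incremental weights `omega`, or
#'   their logs if `log = TRUE`.
#' @param log are `incremental_weights` on the log scale?
#' @return the CESS, in (0, P].
#' @export
cess <- function(normalized_weights, incremental_weights, log = FALSE) {
  w <- normalized_weights
  P <- length(w)
  if (log) {
    lo <- incremental_weights
    if (anyNA(lo)) stop("invalid increments: NaN")
    if (all(!is.finite(lo))) stop("invalid increments: all zero")
    lw <- ifelse(w > 0, base::log(w), -Inf)
    lnum <- 2 * logsumexp(lw + lo)
    lden <- logsumexp(lw + 2 * lo)
    return(P * exp(lnum - lden))
  }
  om <- incremental_weights
  if (anyNA(om) || all(om == 0)) stop("invalid increments: all zero or NaN")
  P * sum(w * om)^2 / sum(w * om^2)
}

#' Annealing configuration
#'
#' @param cess_fraction target CESS as a fraction `beta` of `P` used to place
#'   the next intermediate distribution.
#' @param resample_fraction ESS fraction `alpha` below which stratified
#'   resampling is triggered.
#' @param max_bisection_iters bisection iterations for the gamma search.
#' @param min_gamma_step enforced minimum annealing step.
#' @param cess_tol bisection stops when `|CESS - beta P| <= cess_tol * P`.
#' @param mcmc_iters_per_distribution MCMC sweeps applied after each
#'   tempering step.
#' @return a list of class `anneal_config`.
#' @export
anneal_config <- function(cess_fraction = 0.99, resample_fraction = 0.5,
                          max_bisection_iters = 60L, min_gamma_step = 1e-6,
                          cess_tol = 1e-3, mcmc_iters_per_distribution = 2L) {
  stopifnot(cess_fraction > 0, cess_fraction < 1,
            resample_fraction > 0, resample_fraction < 1,
            min_gamma_step > 0)
  structure(list(cess_fraction = cess_fraction,
                 resample_fraction = resample_fraction,
                 max_bisection_iters = as.integer(max_bisection_iters),
                 min_gamma_step = min_gamma_step,
                 cess_tol = cess_tol,
                 mcmc_iters_per_distribution = as.integer(mcmc_iters_per_distribution)),
            class = "anneal_config")
}

#' Choose the next annealing fraction by bisection on the CESS
#'
#' Finds `gamma* > current_gamma` such that the CESS of the incremental
#' weights for tempering from `current_gamma` to `gamma*` equals
#' `beta * P`, or returns 1 when even the full step keeps the CESS above the
#' target.
#'
#' @param normalized_weights current normalised weights.
#' @param log_increment_at function mapping a candidate `gamma` to the
#'   per-particle *log* incremental weights of tempering from `current_gamma`
#'   to `gamma`.
#' @param current_gamma current annealing fraction, in [0, 1).
#' @param config an [anneal_config()].
#' @return the next annealing fraction, in `(current_gamma, 1]`.
#' @export
adapt_gamma <- function(normalized_weights, log_increment_at, current_gamma,
                        config = anneal_config()) {
  stopifnot(current_gamma < 1)
  P <- length(normalized_weights)
  target <- config$cess_fraction * P
  cess_at <- function(g) {
    val <- tryCatch(cess(normalized_weights, log_increment_at(g), log = TRUE),
                    error = function(e) NaN)
    val
  }
  c1 <- cess_at(1)
  if (is.nan(c1)) {
    warning("CESS not computable at gamma = 1; falling back to minimum step")
    return(min(1, current_gamma + config$min_gamma_step))
  }
  if (c1 >= target) return(1)
  lo <- current_gamma; hi <- 1
  g <- NA_real_
  for (i in seq_len(config$max_bisection_iters)) {
    g <- (lo + hi) / 2
    cg <- cess_at(g)
    if (is.nan(cg)) {
      warning("non-finite CESS during bisection; falling back to minimum step")
      return(min(1, current_gamma + config$min_gamma_step))
    }
    if (abs(cg - target) <= config$cess_tol * P) break
    if (cg > target) lo <- g else hi <- g
  }
  max(g, min(1, current_gamma + config$min_gamma_step))
}

#' Geometric-annealing reweight
#'
#' Increments each particle's log-weight by
#' `(gamma_new - gamma_old) * (log_to - log_from)` and appends the
#' log-mean incremental weight (under the current normalised weights) to the
#' accumulated evidence increments.
#'
#' @param system a [particle_system()].
#' @param log_from per-particle log density under the bridge's start
#'   (transformed-proposal) distribution.
#' @param log_to per-particle log density under the bridge's end target.
#' @param gamma_old,gamma_new old and new annealing fractions.
#' @return the updated particle system.
#' @export
reweight_geometric <- function(system, log_from, log_to, gamma_old, gamma_new) {
  stopifnot(gamma_new > gamma_old)
  log_omega <- (gamma_new - gamma_old) * (log_to - log_from)
  bad <- is.nan(log_omega)
  if (any(bad)) {
    warning(sprintf("%d particle(s) with non-finite density set to zero weight", sum(bad)))
    log_omega[bad] <- -Inf
  }
  ## -Inf - -Inf from already-dead particles: keep dead.
  dead <- !is.finite(system$log_weights)
  log_omega[dead] <- 0
  w <- normalise_log_weights(system$log_weights)
  lw <- ifelse(w > 0, log(w), -Inf)
  increment <- logsumexp(lw + log_omega)
  system$log_weights <- system$log_weights + log_omega
  system$log_evidence_increments <- c(system$log_evidence_increments, increment)
  system$anneal_fraction <- gamma_new
  system
}

#' Stratified resampling indices
#'
#' One uniform draw per stratum `((i-1)/P, i/P]`; the expected copy count of
#' particle `p` is `P * w[p]`.
#'
#' @param normalized_weights normalised weights.
#' @param n number of draws (defaults to `length(normalized_weights)`).
#' @return integer ancestor indices of length `n`.
#' @export
stratified_resample_indices <- function(normalized_weights, n = length(normalized_weights)) {
  w <- normalized_weights
  if (anyNA(w) || any(w < 0)) stop("invalid weights")
  u <- (seq_len(n) - 1 + runif(n)) / n
  cw <- cumsum(w) / sum(w)
  findInterval(u, cw, left.open = TRUE) + 1L
}

#' Accumulated log-evidence estimate
#'
#' Log of the running product-of-averages normalising-constant estimator:
#' `log Z0` plus the sum of all accumulated log increments.
#'
#' @param system a [particle_system()].
#' @return the log-evidence estimate.
#' @export
log_evidence <- function(system) {
  system$log_z0 + sum(system$log_evidence_increments)
}

## Subset/copy particle values by ancestor index, dispatching on the
## container type. Bridges may provide their own `select`.
select_values <- function(values, idx, bridge = NULL) {
  if (!is.null(bridge) && !is.null(bridge$select)) return(bridge$select(values, idx))
  if (is.list(values)) return(values[idx])
  values[idx]
}

#' Run one bridge of a transformation SMC sampler
#'
#' Moves a particle system targeting the bridge's start distribution to its
#' end distribution via a transformation step, adaptive geometric annealing
#' (intermediate distributions placed where the CESS equals `beta * P`),
#' stratified resampling when the ESS drops below `alpha * P`, and MCMC moves
#' invariant for each bridged density.
#'
#' @param system a [particle_system()] currently targeting the bridge's start.
#' @param bridge a model bridge: a list with closures `log_phi_from(values)`,
#'   `log_phi_to(values)` (each returning `P` log-densities), optionally
#'   `transform(values)` (applied once, at the start) and
#'   `select(values, idx)` for resampling.
#' @param mcmc_kernel `function(values, gamma, bridge, weights)` returning
#'   `list(values = ..., accept = mean acceptance rate)`, invariant for the
#'   gamma-bridged density; `NULL` to skip MCMC moves.
#' @param config an [anneal_config()].
#' @param schedule optional fixed annealing schedule: a strictly increasing
#'   vector of fractions ending at 1. When supplied, adaptive placement is
#'   skipped. A schedule frozen from a pilot run restores the exact
#'   unbiasedness of the evidence estimate, which adaptive placement only
#'   attains as `P` grows (the adapted step sizes are correlated with the
#'   incremental weights they average).
#' @return the updated system, with a `bridge_report` data frame attached as
#'   attribute `"report"` recording per-step gamma, ESS, CESS, resampling and
#'   acceptance rates, and the bridge's log evidence-ratio estimate.
#' @export
run_bridge <- function(system, bridge, mcmc_kernel = NULL, config = anneal_config(),
                       schedule = NULL) {
  P <- system$n_particles
  values <- system$values
  if (!is.null(bridge$transform)) values <- bridge$transform(values)
  system$anneal_fraction <- 0
  gamma <- 0
  if (!is.null(schedule)) {
    schedule <- as.numeric(schedule)
    if (length(schedule) < 1 || any(diff(c(0, schedule)) <= 0) ||
        abs(schedule[length(schedule)] - 1) > 1e-12)
      stop("schedule must be strictly increasing and end at 1")
    schedule[length(schedule)] <- 1
  }
  step <- 0L
  rows <- list()
  n_inc0 <- length(system$log_evidence_increments)
  repeat {
    lf <- bridge$log_phi_from(values)
    lt <- bridge$log_phi_to(values)
    if (all(!is.finite(system$log_weights)))
      stop(errorCondition("total particle degeneracy: all weights are zero",
                          class = c("tsmc_numerical_error", "error", "condition")))
    w <- normalise_log_weights(system$log_weights)
    inc_at <- function(g) (g - gamma) * (lt - lf)
    step <- step + 1L
    gamma_new <- if (is.null(schedule)) adapt_gamma(w, inc_at, gamma, config)
                 else schedule[step]
    realised_cess <- cess(w, inc_at(gamma_new), log = TRUE)
    system$values <- values
    system <- reweight_geometric(system, lf, lt, gamma, gamma_new)
    gamma <- gamma_new
    w <- normalise_log_weights(system$log_weights)
    e <- ess(w)
    resampled <- FALSE
    if (e < config$resample_fraction * P) {
      idx <- stratified_resample_indices(w)
      values <- select_values(system$values, idx, bridge)
      system$log_weights <- rep(0, P)
      w <- rep(1 / P, P)
      resampled <- TRUE
    } else {
      values <- system$values
    }
    acc <- NA_real_
    if (!is.null(mcmc_kernel)) {
      accs <- numeric(0)
      for (i in seq_len(config$mcmc_iters_per_distribution)) {
        mk <- mcmc_kernel(values, gamma, bridge, w)
        values <- mk$values
        accs <- c(accs, mk$accept)
      }
      acc <- mean(accs)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model_index = system$model_index, gamma = gamma, ess = e,
      cess = realised_cess, resampled = resampled, accept = acc,
      cum_log_evidence = log_evidence(system))
    if (gamma >= 1) break
  }
  system$values <- values
  system$model_index <- system$model_index + 1L
  report <- do.call(rbind, rows)
  attr(report, "log_evidence_ratio") <-
    sum(system$log_evidence_increments[-seq_len(n_inc0)])
  attr(system, "report") <- report
  system
}
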