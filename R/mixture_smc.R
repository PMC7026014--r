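## Population machinery for the mixture application: particles are stored as
## P x t matrices (means, precisions, weights) so that density evaluations and
## MCMC sweeps vectorise across particles.

.tsmc_counters <- new.env(parent = emptyenv())
.tsmc_counters$gauss_evals <- 0

#' Reset / read the Gaussian density-evaluation counter
#'
#' Counts every scalar Gaussian density evaluated by the mixture likelihood,
#' the dominant cost of all mixture samplers; useful for comparing the
#' computational effort of SMC variants.
#' @return `get_eval_counter()` returns the current count.
#' @export
reset_eval_counter <- function() {
  .tsmc_counters$gauss_evals <- 0
  invisible(NULL)
}

#' @rdname reset_eval_counter
#' @export
get_eval_counter <- function() .tsmc_counters$gauss_evals

## Drop one column per row; l is a scalar or P-vector of column indices.
drop_col <- function(M, l) {
  P <- nrow(M); t1 <- ncol(M)
  j <- matrix(rep(seq_len(t1 - 1L), each = P), P)
  j <- j + (j >= l)
  matrix(M[cbind(rep(seq_len(P), t1 - 1L), as.vector(j))], P)
}

## Row-wise order permutation (ascending), vectorised over rows.
row_order <- function(M) {
  P <- nrow(M); t1 <- ncol(M)
  res <- matrix(0L, P, t1)
  work <- M
  for (k in seq_len(t1)) {
    amin <- max.col(-work, ties.method = "first")
    res[, k] <- amin
    work[cbind(seq_len(P), amin)] <- Inf
  }
  res
}

row_gather <- function(M, ord) {
  P <- nrow(M)
  matrix(M[cbind(rep(seq_len(P), ncol(M)), as.vector(ord))], P)
}

row_logsumexp <- function(M) {
  rmax <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) rmax <- pmax(rmax, M[, k])
  out <- rmax + log(rowSums(exp(M - rmax)))
  out[!is.finite(rmax)] <- -Inf
  out
}

#' Create a mixture particle population
#'
#' @param mu,tau,nu `P x t` matrices of means, precisions and weights.
#' @param birth_pos,children transformation bookkeeping carried by bridges.
#' @return a list of class `mixture_particles`.
#' @export
mixture_particles <- function(mu, tau, nu, birth_pos = NULL, children = NULL) {
  structure(list(mu = mu, tau = tau, nu = nu,
                 birth_pos = birth_pos, children = children),
            class = "mixture_particles")
}

select_mixture_particles <- function(v, idx) {
  mixture_particles(v$mu[idx, , drop = FALSE], v$tau[idx, , drop = FALSE],
                    v$nu[idx, , drop = FALSE],
                    birth_pos = v$birth_pos[idx],
                    children = if (!is.null(v$children)) v$children[idx, , drop = FALSE])
}

## P-vector mixture log-likelihood for matrix-stored particles.
mix_loglik_mat <- function(y, mu, tau, nu) {
  P <- nrow(mu); N <- length(y)
  if (N == 0) return(numeric(P))
  ym <- matrix(y, P, N, byrow = TRUE)
  acc <- matrix(0, P, N)
  for (s in seq_len(ncol(mu))) {
    sdv <- 1 / sqrt(tau[, s])
    z <- (ym - mu[, s]) / sdv
    acc <- acc + nu[, s] * exp(-0.5 * z * z) / (sdv * sqrt(2 * pi))
  }
  .tsmc_counters$gauss_evals <- .tsmc_counters$gauss_evals + P * N * ncol(mu)
  rowSums(log(acc))
}

## Log ordered-prior density (normalised: includes the t! ordering factor and
## the flat-Dirichlet constant), -Inf off support.
mix_log_prior_mat <- function(mu, tau, nu, priors) {
  t1 <- ncol(mu); P <- nrow(mu)
  ok <- rowSums(tau > 0) == t1 & rowSums(nu > 0) == t1 &
    abs(rowSums(nu) - 1) < 1e-9
  if (t1 > 1)
    ok <- ok & rowSums(mu[, -1, drop = FALSE] > mu[, -t1, drop = FALSE]) == t1 - 1
  lp <- rowSums(dnorm(mu, priors$mu_mean, priors$mu_sd, log = TRUE)) +
    rowSums(dgamma(pmax(tau, 1e-300), priors$tau_shape, rate = priors$tau_rate,
                   log = TRUE)) +
    lgamma(t1) + lfactorial(t1)
  lp[!ok] <- -Inf
  lp
}

## Unnormalised log-posterior, P-vector; integrates to the marginal likelihood.
mix_log_target_mat <- function(v, data, priors) {
  lp <- mix_log_prior_mat(v$mu, v$tau, v$nu, priors)
  fin <- is.finite(lp)
  if (any(fin)) {
    ll <- mix_loglik_mat(data$y, v$mu[fin, , drop = FALSE],
                         v$tau[fin, , drop = FALSE], v$nu[fin, , drop = FALSE])
    lp[fin] <- lp[fin] + ll
  }
  lp
}

## Contribution of merging columns (i, j) (i left of j in the sorted state):
## log pi_t(merged state) + log psi(u) - log|J_forward| per particle; -Inf
## where the pair is not in the image of a split. With `validity_only = TRUE`
## returns a logical vector instead.
merge_pair_contrib <- function(v, i, j, data, priors, validity_only = FALSE) {
  P <- nrow(v$mu)
  if (length(i) == 1) i <- rep.int(as.integer(i), P)
  if (length(j) == 1) j <- rep.int(as.integer(j), P)
  pi_idx <- cbind(seq_len(P), i); pj_idx <- cbind(seq_len(P), j)
  mu1 <- v$mu[pi_idx]; mu2 <- v$mu[pj_idx]
  tau1 <- v$tau[pi_idx]; tau2 <- v$tau[pj_idx]
  nu1 <- v$nu[pi_idx]; nu2 <- v$nu[pj_idx]
  s1 <- 1 / tau1; s2 <- 1 / tau2
  nu <- nu1 + nu2
  mu <- (nu1 * mu1 + nu2 * mu2) / nu
  svar <- (nu1 * (mu1^2 + s1) + nu2 * (mu2^2 + s2)) / nu - mu^2
  svar_pos <- pmax(svar, 1e-300)
  u1 <- nu1 / nu
  u2 <- (mu - mu1) / (sqrt(svar_pos) * sqrt(nu2 / nu1))
  u3 <- s1 * nu1 / ((1 - u2^2) * svar_pos * nu)
  ok <- is.finite(svar) & svar > 0 & mu1 < mu2 &
    u2 > 0 & u2 < 1 & u3 > 0 & u3 < 1
  if (validity_only) return(ok)
  ## merged t-component state: drop column j, overwrite column i, re-sort
  mur <- drop_col(v$mu, j); taur <- drop_col(v$tau, j); nur <- drop_col(v$nu, j)
  ridx <- cbind(seq_len(P), i)  # i < j so position i survives the drop
  mur[ridx] <- mu; taur[ridx] <- 1 / svar_pos; nur[ridx] <- nu
  ord <- row_order(mur)
  vt <- mixture_particles(row_gather(mur, ord), row_gather(taur, ord),
                          row_gather(nur, ord))
  base <- mix_log_target_mat(vt, data, priors)
  lpsi <- dbeta(pmin(pmax(u1, 1e-300), 1 - 1e-16), 2, 2, log = TRUE) +
    dbeta(pmin(pmax(u2, 1e-300), 1 - 1e-16), 2, 2, log = TRUE)
  ljac <- log(nu) + log(pmax(mu2 - mu1, 1e-300)) + log(tau1) + log(tau2) -
    log(pmax(u2, 1e-300)) - log1p(-pmin(u2, 1 - 1e-16)^2) -
    log(pmax(u3, 1e-300)) - log1p(-pmin(u3, 1 - 1e-16)) + log(svar_pos)
  out <- base + lpsi - ljac
  out[!ok] <- -Inf
  out
}

## Number of valid merge pairs per particle (the size of the support of the
## target-side label distribution in conditional mode).
count_valid_pairs <- function(v, data, priors) {
  t1 <- ncol(v$mu)
  cnt <- integer(nrow(v$mu))
  for (i in seq_len(t1 - 1)) for (j in seq((i + 1), t1))
    cnt <- cnt + merge_pair_contrib(v, i, j, data, priors, validity_only = TRUE)
  cnt
}

#' Model bridge for one mixture model transition
#'
#' Builds the bridge from the t-component to the (t+1)-component posterior.
#' The birth move inserts a fresh prior-drawn component (a single route); the
#' split move moment-matches a uniformly chosen component into two children
#' (`t` routes). In `"conditional"` mode the route draw is kept with the
#' particle (the labelled children/new-component positions) and the weight
#' update follows the conditional form; in `"marginal"` mode the proposal
#' density is summed over every inverse image (all component pairs whose
#' merge exists for split; all deletion positions for birth), the
#' Rao-Blackwellised form.
#'
#' @param t current number of components (`1 <= t < max_components`).
#' @param move `"birth"` or `"split"`.
#' @param mode `"conditional"` or `"marginal"`.
#' @param priors a [mixture_priors()].
#' @param data a [mixture_dataset()].
#' @return a bridge usable with [run_bridge()].
#' @export
bridge_for_transition <- function(t, move = c("split", "birth"),
                                  mode = c("marginal", "conditional"),
                                  priors, data) {
  move <- match.arg(move); mode <- match.arg(mode)
  t <- as.integer(t)
  stopifnot(t >= 1, t < priors$max_components)

  transform <- function(v) {
    P <- nrow(v$mu)
    if (move == "birth") {
      mu_new <- rnorm(P, priors$mu_mean, priors$mu_sd)
      tau_new <- rgamma(P, priors$tau_shape, rate = priors$tau_rate)
      nu_new <- rbeta(P, 1, t)
      mu2 <- cbind(v$mu, mu_new)
      tau2 <- cbind(v$tau, tau_new)
      nu2 <- cbind(v$nu * (1 - nu_new), nu_new)
      ord <- row_order(mu2)
      pos <- max.col(ord == t + 1L, ties.method = "first")
      mixture_particles(row_gather(mu2, ord), row_gather(tau2, ord),
                        row_gather(nu2, ord), birth_pos = pos)
    } else {
      l <- if (t == 1L) rep(1L, P) else sample.int(t, P, replace = TRUE)
      u1 <- rbeta(P, 2, 2); u2 <- rbeta(P, 2, 2); u3 <- runif(P)
      pidx <- cbind(seq_len(P), l)
      sp <- rg_split_values(v$mu[pidx], v$tau[pidx], v$nu[pidx], u1, u2, u3)
      mu2 <- cbind(drop_col2(v$mu, l, t), sp$mu1, sp$mu2)
      tau2 <- cbind(drop_col2(v$tau, l, t), sp$tau1, sp$tau2)
      nu2 <- cbind(drop_col2(v$nu, l, t), sp$nu1, sp$nu2)
      ord <- row_order(mu2)
      ch <- cbind(max.col(ord == t, ties.method = "first"),
                  max.col(ord == t + 1L, ties.method = "first"))
      mixture_particles(row_gather(mu2, ord), row_gather(tau2, ord),
                        row_gather(nu2, ord), children = ch)
    }
  }

  log_phi_from <- function(v) {
    if (move == "birth" && mode == "conditional") {
      P <- nrow(v$mu)
      l <- v$birth_pos
      idx <- cbind(seq_len(P), l)
      nl <- v$nu[idx]; ml <- v$mu[idx]; tl <- v$tau[idx]
      vt <- mixture_particles(drop_col(v$mu, l), drop_col(v$tau, l),
                              drop_col(v$nu, l) / (1 - nl))
      mix_log_target_mat(vt, data, priors) +
        dnorm(ml, priors$mu_mean, priors$mu_sd, log = TRUE) +
        dgamma(tl, priors$tau_shape, rate = priors$tau_rate, log = TRUE) +
        dbeta(nl, 1, t, log = TRUE) - (t - 1) * log1p(-nl)
    } else if (move == "birth") {
      ## marginalise over the deletion position
      contrib <- matrix(-Inf, nrow(v$mu), t + 1L)
      for (l in seq_len(t + 1L)) {
        nl <- v$nu[, l]; ml <- v$mu[, l]; tl <- v$tau[, l]
        vt <- mixture_particles(drop_col(v$mu, l), drop_col(v$tau, l),
                                drop_col(v$nu, l) / (1 - nl))
        contrib[, l] <- mix_log_target_mat(vt, data, priors) +
          dnorm(ml, priors$mu_mean, priors$mu_sd, log = TRUE) +
          dgamma(tl, priors$tau_shape, rate = priors$tau_rate, log = TRUE) +
          dbeta(nl, 1, t, log = TRUE) - (t - 1) * log1p(-nl)
      }
      row_logsumexp(contrib)
    } else if (mode == "conditional") {
      ## the route prior rho(l) = 1/t stays in the proposal density: the
      ## target-side label distribution (uniform over valid merge pairs)
      ## differs from rho after re-sorting, so they do not cancel
      merge_pair_contrib(v, v$children[, 1], v$children[, 2], data, priors) -
        log(t)
    } else {
      pairs <- utils::combn(t + 1L, 2L)
      contrib <- matrix(-Inf, nrow(v$mu), ncol(pairs))
      for (k in seq_len(ncol(pairs)))
        contrib[, k] <- merge_pair_contrib(v, pairs[1, k], pairs[2, k],
                                           data, priors) - log(t)
      row_logsumexp(contrib)
    }
  }

  ## conditional modes carry a degenerate label whose (normalised) target-side
  ## distribution enters the extended target: uniform over the valid labels.
  log_phi_to <- function(v) {
    base <- mix_log_target_mat(v, data, priors)
    if (mode == "conditional") {
      if (move == "birth") base - log(t + 1)
      else base - log(pmax(count_valid_pairs(v, data, priors), 1L))
    } else base
  }

  structure(list(transform = transform,
                 log_phi_from = log_phi_from,
                 log_phi_to = log_phi_to,
                 select = select_mixture_particles,
                 move = move, route_mode = mode, t = t),
            class = "tsmc_bridge")
}

## drop_col for per-row indices when l is a vector and original width is t
drop_col2 <- function(M, l, t) {
  if (t == 1L) return(matrix(numeric(0), nrow(M), 0))
  drop_col(M, l)
}

#' Metropolis-within-Gibbs kernel for mixture particle populations
#'
#' One sweep updates, for every particle in parallel: each component mean
#' (Gaussian random walk), each log-precision (log-scale random walk with the
#' Hastings correction), and each additive-log-ratio weight coordinate.
#' Proposals violating the ordering constraint are rejected through the
#' target's support indicator. Proposal scales are `2.38` times the weighted
#' population standard deviation of each coordinate, re-tuned at every call.
#'
#' @param values a [mixture_particles()] population.
#' @param gamma annealing fraction of the current bridged density.
#' @param bridge the active bridge (supplies `log_phi_from` / `log_phi_to`).
#' @param weights normalised particle weights (used for scale tuning).
#' @return `list(values, accept)`.
#' @export
mixture_mcmc_kernel <- function(values, gamma, bridge, weights) {
  P <- nrow(values$mu); t1 <- ncol(values$mu)
  ld <- function(v) {
    if (gamma >= 1) bridge$log_phi_to(v)
    else gamma * bridge$log_phi_to(v) + (1 - gamma) * bridge$log_phi_from(v)
  }
  wsd <- function(x) {
    m <- sum(weights * x)
    sqrt(max(sum(weights * (x - m)^2), 1e-12))
  }
  cur <- ld(values)
  acc_n <- 0; acc_d <- 0
  for (s in seq_len(t1)) {  # means
    v2 <- values
    v2$mu[, s] <- values$mu[, s] + rnorm(P, 0, 2.38 * wsd(values$mu[, s]))
    new <- ld(v2)
    d <- new - cur
    d[is.nan(d)] <- -Inf  # dead particle: both densities are zero
    a <- log(runif(P)) < d
    values$mu[a, s] <- v2$mu[a, s]; cur[a] <- new[a]
    acc_n <- acc_n + sum(a); acc_d <- acc_d + P
  }
  for (s in seq_len(t1)) {  # log-precisions
    v2 <- values
    lt <- log(values$tau[, s])
    v2$tau[, s] <- exp(lt + rnorm(P, 0, 2.38 * wsd(lt)))
    new <- ld(v2)
    d <- new - cur + log(v2$tau[, s]) - lt
    d[is.nan(d)] <- -Inf
    a <- log(runif(P)) < d
    values$tau[a, s] <- v2$tau[a, s]; cur[a] <- new[a]
    acc_n <- acc_n + sum(a); acc_d <- acc_d + P
  }
  if (t1 > 1) {
    z <- log(values$nu[, -t1, drop = FALSE] / values$nu[, t1])
    for (s in seq_len(t1 - 1L)) {  # ALR weight coordinates
      z2 <- z
      z2[, s] <- z[, s] + rnorm(P, 0, 2.38 * wsd(z[, s]))
      expz <- cbind(exp(z2), 1)
      v2 <- values
      v2$nu <- expz / rowSums(expz)
      new <- ld(v2)
      jac <- rowSums(log(v2$nu)) - rowSums(log(values$nu))
      a <- is.finite(new) & (log(runif(P)) < (new - cur + jac))
      values$nu[a, ] <- v2$nu[a, , drop = FALSE]; cur[a] <- new[a]
      z[a, ] <- z2[a, , drop = FALSE]
      acc_n <- acc_n + sum(a); acc_d <- acc_d + P
    }
  }
  list(values = values, accept = acc_n / acc_d)
}

#' Log-evidence of one mixture model by prior-to-posterior annealing (SMC2)
#'
#' Anneals from the ordered prior to the t-component posterior with the same
#' adaptive CESS machinery as the transformation bridges (an identity
#' transform). Returns the log marginal likelihood of model `t`.
#'
#' @param t number of components.
#' @param data a [mixture_dataset()], or `NULL` for no observations (in which
#'   case the evidence is exactly 1).
#' @param priors a [mixture_priors()].
#' @param n_particles number of particles.
#' @param config an [anneal_config()].
#' @param return_system return the full [particle_system()] (with the
#'   bridge report attached) instead of just the log evidence?
#' @return the log-evidence, or the final particle system.
#' @export
smc2_evidence <- function(t, data, priors, n_particles = 500L,
                          config = anneal_config(), return_system = FALSE) {
  P <- as.integer(n_particles)
  if (is.null(data)) data <- list(y = numeric(0), n = 0L)
  mu <- matrix(rnorm(P * t, priors$mu_mean, priors$mu_sd), P)
  if (t > 1) mu <- row_gather(mu, row_order(mu))
  tau <- matrix(rgamma(P * t, priors$tau_shape, rate = priors$tau_rate), P)
  e <- matrix(rexp(P * t), P)
  nu <- e / rowSums(e)
  values <- mixture_particles(mu, tau, nu)
  bridge <- structure(list(
    transform = NULL,
    log_phi_from = function(v) mix_log_prior_mat(v$mu, v$tau, v$nu, priors),
    log_phi_to = function(v) mix_log_target_mat(v, data, priors),
    select = select_mixture_particles), class = "tsmc_bridge")
  sys <- particle_system(values, P, model_index = t)
  sys <- run_bridge(sys, bridge, mixture_mcmc_kernel, config)
  if (return_system) sys else log_evidence(sys)
}

#' Transformation SMC over a sequence of mixture models
#'
#' Estimates the log marginal likelihood of every model `t = 1..max_components`
#' by computing the model-1 evidence with prior-to-posterior annealing and then
#' chaining transformation bridges (birth or split; conditional or marginal
#' weights) that carry the particle population from each posterior to the
#' next, accumulating log Bayes factors.
#'
#' @param data a [mixture_dataset()] or numeric vector of observations.
#' @param max_components largest model `T`.
#' @param move,mode transformation and weight-update variant, see
#'   [bridge_for_transition()].
#' @param n_particles number of particles (default 500).
#' @param config an [anneal_config()] (default `beta = 0.99`, `alpha = 0.5`).
#' @return a list with `log_evidence` (named vector over models),
#'   `reports` (per-bridge diagnostics), `n_gauss_evals`, and the final
#'   `system`.
#' @export
tsmc_mixture <- function(data, max_components = 8L,
                         move = c("split", "birth"),
                         mode = c("marginal", "conditional"),
                         n_particles = 500L, config = anneal_config()) {
  move <- match.arg(move); mode <- match.arg(mode)
  if (!inherits(data, "mixture_dataset")) data <- mixture_dataset(data)
  priors <- mixture_priors(data, max_components)
  reset_eval_counter()
  sys <- smc2_evidence(1L, data, priors, n_particles, config,
                       return_system = TRUE)
  logz <- numeric(max_components)
  logz[1] <- log_evidence(sys)
  reports <- list(attr(sys, "report"))
  for (t in seq_len(max_components - 1L)) {
    bridge <- bridge_for_transition(t, move, mode, priors, data)
    sys <- run_bridge(sys, bridge, mixture_mcmc_kernel, config)
    reports[[t + 1L]] <- attr(sys, "report")
    logz[t + 1L] <- logz[t] +
      attr(attr(sys, "report"), "log_evidence_ratio")
  }
  names(logz) <- seq_len(max_components)
  list(log_evidence = logz, reports = reports,
       n_gauss_evals = get_eval_counter(), system = sys)
}
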