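#' Describe one transformation route
#'
#' A route is one deterministic transformation between neighbouring model
#' spaces, together with the distribution of the auxiliary variables it
#' consumes and the Jacobian bookkeeping needed for weight updates. States are
#' arbitrary R objects; `forward` maps `(state, u)` to the new-space state,
#' `inverse` maps a new-space state back to `list(state =, u =)` or `NULL`
#' when the point has no preimage under this route.
#'
#' @param forward `function(state, u)` returning the transformed state.
#' @param inverse `function(new_state)` returning `list(state, u)` or `NULL`.
#' @param log_jac_inverse `function(new_state)` log absolute Jacobian
#'   determinant of the inverse map at `new_state` (0 for measure-preserving
#'   or purely discrete maps).
#' @param sample_u `function(state)` drawing the auxiliary variables (may
#'   return `NULL` when the route needs none).
#' @param log_psi `function(u, state)` log density of the auxiliary draw
#'   (must return 0 when `u` is `NULL`).
#' @param prior route prior mass `rho(l)`.
#' @return a list of class `tsmc_route`.
#' @export
new_route <- function(forward, inverse, log_jac_inverse = function(new_state) 0,
                      sample_u = function(state) NULL,
                      log_psi = function(u, state) 0,
                      prior = 1) {
  structure(list(forward = forward, inverse = inverse,
                 log_jac_inverse = log_jac_inverse,
                 sample_u = sample_u, log_psi = log_psi, prior = prior),
            class = "tsmc_route")
}

#' Build a generic model bridge from unnormalised targets and routes
#'
#' Particle values for this bridge are a plain list of states. In
#' `"conditional"` mode the sampled route index is carried with each particle
#' (as attribute `route`) and the proposal density is evaluated through that
#' route's inverse; in `"marginal"` mode the proposal density sums
#' `rho(m) * psi(u_m) * |J_m|` over every route whose inverse image exists
#' (the Rao-Blackwellised update). The two coincide exactly when a single
#' route is registered.
#'
#' @param log_target_from `function(state)` log unnormalised density of the
#'   start target (old model space).
#' @param log_target_to `function(state)` log unnormalised density of the end
#'   target (new model space).
#' @param routes list of [new_route()] objects; route priors must sum to 1.
#' @param mode `"conditional"` or `"marginal"`.
#' @return a bridge usable with [run_bridge()].
#' @export
route_bridge <- function(log_target_from, log_target_to, routes,
                         mode = c("conditional", "marginal")) {
  mode <- match.arg(mode)
  rho <- vapply(routes, function(r) r$prior, numeric(1))
  if (abs(sum(rho) - 1) > 1e-9) stop("route prior masses must sum to 1")
  M <- length(routes)

  transform <- function(values) {
    lapply(values, function(state) {
      l <- if (M == 1L) 1L else sample.int(M, 1L, prob = rho)
      u <- routes[[l]]$sample_u(state)
      new_state <- routes[[l]]$forward(state, u)
      attr(new_state, "route") <- l
      new_state
    })
  }

  ## log proposal density of one transformed state; route = integer for the
  ## conditional form, NA for the marginalised form.
  log_q <- function(new_state, route = NA) {
    one <- function(m, with_rho) {
      inv <- routes[[m]]$inverse(new_state)
      if (is.null(inv)) return(-Inf)
      log_target_from(inv$state) + routes[[m]]$log_psi(inv$u, inv$state) +
        routes[[m]]$log_jac_inverse(new_state) +
        if (with_rho) log(rho[m]) else 0
    }
    if (!is.na(route)) return(one(route, with_rho = FALSE))
    logsumexp(vapply(seq_len(M), one, numeric(1), with_rho = TRUE))
  }

  structure(list(
    transform = transform,
    log_phi_from = function(values) {
      vapply(values, function(s) {
        l <- if (mode == "conditional") attr(s, "route") else NA
        log_q(s, l)
      }, numeric(1))
    },
    log_phi_to = function(values) vapply(values, log_target_to, numeric(1)),
    log_q = log_q,
    routes = routes, route_mode = mode,
    log_target_from = log_target_from, log_target_to = log_target_to
  ), class = "tsmc_bridge")
}

#' Apply a bridge's transformation step to a particle system
#'
#' Draws fresh auxiliary variables and (in conditional mode) a route for each
#' particle, and applies the corresponding forward transformation. Weights are
#' untouched: the weight change happens in the subsequent reweighting.
#'
#' @param system a [particle_system()].
#' @param bridge a bridge with a `transform` closure.
#' @return the system with transformed values and `anneal_fraction` reset to 0.
#' @export
transform_step <- function(system, bridge) {
  if (!is.null(bridge$transform)) system$values <- bridge$transform(system$values)
  system$anneal_fraction <- 0
  system
}

#' Log proposal density of a transformed state under a bridge
#'
#' Conditional form: the density of the state's inverse image through one
#' route, `log[pi_t(theta) psi(u)] + log|J_inv|`. Marginal form
#' (`route = NA`): the log of the sum of `rho(m)`-weighted contributions over
#' all routes with an inverse image; routes without one contribute zero.
#'
#' @param bridge a [route_bridge()].
#' @param transformed_state a state in the new model space.
#' @param route integer route index, or `NA` for the marginalised density.
#' @return a log density (possibly `-Inf` when no route admits an inverse
#'   image, in which case the particle is killed downstream).
#' @export
log_proposal_density <- function(bridge, transformed_state, route = NA) {
  bridge$log_q(transformed_state, route)
}

#' A trivial bridge between two targets on the same space
#'
#' No transformation, no auxiliary variables: anneal geometrically from
#' `log_target_from` to `log_target_to`. Used for prior-to-posterior
#' annealing (SMC2-style runs) and tractable test targets.
#'
#' @param log_target_from,log_target_to vectorised `function(values)` returning
#'   `P` log unnormalised densities when `vectorised = TRUE`, otherwise
#'   per-state functions applied over a list/vector of states.
#' @param vectorised do the density functions act on the whole population?
#' @param select optional `function(values, idx)` resampling subset.
#' @return a bridge usable with [run_bridge()].
#' @export
identity_bridge <- function(log_target_from, log_target_to, vectorised = TRUE,
                            select = NULL) {
  wrap <- function(f) {
    if (vectorised) f
    else function(values) vapply(values, f, numeric(1))
  }
  structure(list(transform = NULL,
                 log_phi_from = wrap(log_target_from),
                 log_phi_to = wrap(log_target_to),
                 select = select),
            class = "tsmc_bridge")
}

#' Random-walk Metropolis kernel for numeric-vector particle populations
#'
#' A simple kernel for bridges whose particle values are a numeric vector
#' (one scalar per particle): one Gaussian random-walk update per particle,
#' accepted against the gamma-bridged density. Used by tractable test targets.
#'
#' @param scale proposal standard deviation; `NULL` to use 2.38 times the
#'   weighted population standard deviation.
#' @return a kernel `function(values, gamma, bridge, weights)`.
#' @export
rw_kernel_numeric <- function(scale = NULL) {
  function(values, gamma, bridge, weights) {
    s <- scale
    if (is.null(s)) {
      mu <- sum(weights * values)
      s <- 2.38 * sqrt(max(sum(weights * (values - mu)^2), 1e-12))
    }
    ld <- function(v) gamma * bridge$log_phi_to(v) + (1 - gamma) * bridge$log_phi_from(v)
    cur <- ld(values)
    prop <- values + rnorm(length(values), 0, s)
    new <- ld(prop)
    acc <- log(runif(length(values))) < (new - cur)
    values[acc] <- prop[acc]
    list(values = values, accept = mean(acc))
  }
}
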