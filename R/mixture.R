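#' Univariate Gaussian mixture dataset
#'
#' Wraps observations together with the two summaries the default priors are
#' built from: the sample mean `m` and the range `S = max(y) - min(y)`.
#'
#' @param y numeric observations.
#' @return a list of class `mixture_dataset` with fields `y`, `n`, `m`, `S`.
#' @export
mixture_dataset <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 1 || anyNA(y)) stop("need at least one non-missing observation")
  S <- diff(range(y))
  if (length(y) >= 2 && S <= 0) stop("data range must be positive")
  structure(list(y = y, n = length(y), m = mean(y), S = S),
            class = "mixture_dataset")
}

#' Data-driven priors for the mixture model
#'
#' Component means are a priori `Normal(m, S^2)`, precisions
#' `Gamma(2, 2 S^2 / 100)` (shape/rate), weights jointly flat Dirichlet, and
#' the number of components uniform on `1..max_components`; `m` and `S` are
#' the mean and range of the data.
#'
#' @param data a [mixture_dataset()].
#' @param max_components largest model considered.
#' @return a list of class `mixture_priors`.
#' @export
mixture_priors <- function(data, max_components = 8L) {
  structure(list(mu_mean = data$m, mu_sd = data$S,
                 tau_shape = 2, tau_rate = 2 * data$S^2 / 100,
                 max_components = as.integer(max_components)),
            class = "mixture_priors")
}

#' Mixture parameters for a t-component model
#'
#' Means must be strictly increasing (the ordering constraint used for
#' identifiability), precisions positive, and weights positive summing to one.
#'
#' @param means,precisions,weights numeric vectors of equal length.
#' @return a list of class `mixture_params`.
#' @export
mixture_params <- function(means, precisions, weights) {
  t <- length(means)
  stopifnot(length(precisions) == t, length(weights) == t)
  if (t > 1 && any(diff(means) <= 0)) stop("means must be strictly increasing")
  if (any(precisions <= 0)) stop("precisions must be positive")
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be positive and sum to one")
  structure(list(means = means, precisions = precisions, weights = weights),
            class = "mixture_params")
}

#' Mixture log-likelihood
#'
#' `sum_i log sum_s nu_s N(y_i | mu_s, 1/tau_s)`.
#'
#' @param params a [mixture_params()].
#' @param data a [mixture_dataset()].
#' @return the log-likelihood.
#' @export
mix_log_likelihood <- function(params, data) {
  dens <- vapply(seq_along(params$means), function(s) {
    params$weights[s] * dnorm(data$y, params$means[s], 1 / sqrt(params$precisions[s]))
  }, numeric(data$n))
  if (data$n == 1) dens <- matrix(dens, nrow = 1)
  sum(log(rowSums(dens)))
}

#' Unnormalised mixture log-posterior
#'
#' Log prior (including the ordering-constraint indicator and the
#' normalisation of the ordered prior) plus log-likelihood. The value
#' integrates to the marginal likelihood of the t-component model, so
#' differences across t are log Bayes factors.
#'
#' @param params a list with `means`, `precisions`, `weights` (not
#'   necessarily passing [mixture_params()] validation: out-of-order means
#'   return `-Inf`).
#' @inheritParams mix_log_likelihood
#' @param priors a [mixture_priors()].
#' @return the unnormalised log posterior density (`-Inf` off support).
#' @export
mix_log_posterior <- function(params, data, priors) {
  t <- length(params$means)
  if ((t > 1 && any(diff(params$means) <= 0)) || any(params$precisions <= 0) ||
      any(params$weights <= 0) || abs(sum(params$weights) - 1) > 1e-9)
    return(-Inf)
  lp <- sum(dnorm(params$means, priors$mu_mean, priors$mu_sd, log = TRUE)) +
    sum(dgamma(params$precisions, priors$tau_shape, rate = priors$tau_rate, log = TRUE)) +
    lgamma(t) +        # flat Dirichlet density
    lfactorial(t)      # normalisation of the ordered prior
  lp + mix_log_likelihood(params, data)
}

#' Birth transformation: insert a freshly drawn component
#'
#' The auxiliary draw is `u = (mu*, tau*, nu*)` with `mu* ~ p_mu`,
#' `tau* ~ p_tau` and the new weight `nu* ~ Beta(1, t)` (stick-breaking);
#' existing weights are rescaled by `1 - nu*` and the components re-sorted by
#' mean. The forward log Jacobian is `(t - 1) * log(1 - nu*)`.
#'
#' @param params_t a [mixture_params()] with `t` components.
#' @param u list with `mu`, `tau`, `nu` (drawn if `NULL`).
#' @param priors a [mixture_priors()] (used only when drawing `u`).
#' @return list with the `t+1`-component `params`, the drawn `u`, the new
#'   component's post-sort `position`, and `log_jac_forward`.
#' @export
birth_route <- function(params_t, u = NULL, priors = NULL) {
  t <- length(params_t$means)
  if (is.null(u)) {
    u <- list(mu = rnorm(1, priors$mu_mean, priors$mu_sd),
              tau = rgamma(1, priors$tau_shape, rate = priors$tau_rate),
              nu = rbeta(1, 1, t))
  }
  means <- c(params_t$means, u$mu)
  precisions <- c(params_t$precisions, u$tau)
  weights <- c(params_t$weights * (1 - u$nu), u$nu)
  ord <- order(means)
  list(params = mixture_params(means[ord], precisions[ord], weights[ord]),
       u = u, position = which(ord == t + 1L),
       log_jac_forward = (t - 1) * log1p(-u$nu))
}

#' Inverse of the birth transformation
#'
#' Deletes component `position` and rescales the remaining weights.
#'
#' @param params_t1 the `t+1`-component parameters.
#' @param position index of the component that was born.
#' @return list with the `t`-component `params` and the recovered `u`.
#' @export
birth_inverse <- function(params_t1, position) {
  nu <- params_t1$weights[position]
  list(params = mixture_params(params_t1$means[-position],
                               params_t1$precisions[-position],
                               params_t1$weights[-position] / (1 - nu)),
       u = list(mu = params_t1$means[position],
                tau = params_t1$precisions[position], nu = nu))
}

## Richardson-Green moment-matching split of one component, in precision
## coordinates. Moment equations (sigma^2 = 1/tau):
##   nu1 = u1 nu*,                nu2 = (1-u1) nu*
##   mu1 = mu* - u2 s* sqrt(nu2/nu1),  mu2 = mu* + u2 s* sqrt(nu1/nu2)
##   s1^2 = u3 (1-u2^2) s*^2 nu*/nu1,  s2^2 = (1-u3)(1-u2^2) s*^2 nu*/nu2
## preserving nu1+nu2, nu1 mu1 + nu2 mu2 and nu1(mu1^2+s1^2)+nu2(mu2^2+s2^2).
rg_split_values <- function(mu, tau, nu, u1, u2, u3) {
  s2 <- 1 / tau
  nu1 <- u1 * nu; nu2 <- (1 - u1) * nu
  d1 <- u2 * sqrt(s2) * sqrt(nu2 / nu1)
  d2 <- u2 * sqrt(s2) * sqrt(nu1 / nu2)
  mu1 <- mu - d1; mu2 <- mu + d2
  s1 <- u3 * (1 - u2^2) * s2 * nu / nu1
  s2b <- (1 - u3) * (1 - u2^2) * s2 * nu / nu2
  list(mu1 = mu1, mu2 = mu2, tau1 = 1 / s1, tau2 = 1 / s2b,
       nu1 = nu1, nu2 = nu2)
}

## log |J| of the split map in precision coordinates:
## |J_var| = nu* |mu1-mu2| s1^2 s2^2 / (u2 (1-u2^2) u3 (1-u3) s*^2),
## chain-ruled through sigma^2 = 1/tau on both sides:
## |J_tau| = |J_var| tau1^2 tau2^2 / tau*^2.
rg_split_log_jac <- function(mu, tau, nu, u1, u2, u3, sp) {
  log(nu) + log(sp$mu2 - sp$mu1) + log(sp$tau1) + log(sp$tau2) -
    log(u2) - log1p(-u2^2) - log(u3) - log1p(-u3) - log(tau)
}

#' Split transformation: moment-matching split of one component
#'
#' Splits component `component` into two children that preserve its weight
#' and first two moments, using auxiliary draws `u1 ~ Beta(2,2)` (weight
#' fraction), `u2 ~ Beta(2,2)` (mean separation) and `u3 ~ Beta(1,1)`
#' (variance share). Children are re-sorted with the full component list.
#'
#' @param params_t a [mixture_params()] with `t` components.
#' @param component index of the component to split.
#' @param u list with `u1`, `u2`, `u3` in (0,1) (drawn if `NULL`).
#' @return list with the `t+1`-component `params`, the drawn `u`, the
#'   post-sort `children` positions (low-mean child first), and
#'   `log_jac_forward`.
#' @export
split_route <- function(params_t, component, u = NULL) {
  t <- length(params_t$means)
  l <- component
  if (is.null(u)) u <- list(u1 = rbeta(1, 2, 2), u2 = rbeta(1, 2, 2), u3 = runif(1))
  sp <- rg_split_values(params_t$means[l], params_t$precisions[l],
                        params_t$weights[l], u$u1, u$u2, u$u3)
  means <- c(params_t$means[-l], sp$mu1, sp$mu2)
  precisions <- c(params_t$precisions[-l], sp$tau1, sp$tau2)
  weights <- c(params_t$weights[-l], sp$nu1, sp$nu2)
  ord <- order(means)
  list(params = mixture_params(means[ord], precisions[ord], weights[ord]),
       u = u,
       children = c(which(ord == t), which(ord == t + 1L)),
       log_jac_forward = rg_split_log_jac(params_t$means[l], params_t$precisions[l],
                                          params_t$weights[l], u$u1, u$u2, u$u3, sp))
}

#' Merge two components (inverse of the split transformation)
#'
#' Moment-matching merge of components `i` and `j` (`i` must have the smaller
#' mean). Returns `NULL` when the recovered auxiliary values fall outside
#' (0,1), i.e. when the pair is not in the image of any split.
#'
#' @param params_t1 the `t+1`-component parameters.
#' @param i,j positions of the two putative children.
#' @return `NULL`, or a list with the merged `params`, the merged component's
#'   position `l`, the recovered `u`, and `log_jac_forward` of the matching
#'   split.
#' @export
merge_components <- function(params_t1, i, j) {
  if (params_t1$means[i] >= params_t1$means[j]) return(NULL)
  nu1 <- params_t1$weights[i]; nu2 <- params_t1$weights[j]
  mu1 <- params_t1$means[i]; mu2 <- params_t1$means[j]
  s1 <- 1 / params_t1$precisions[i]; s2b <- 1 / params_t1$precisions[j]
  nu <- nu1 + nu2
  mu <- (nu1 * mu1 + nu2 * mu2) / nu
  svar <- (nu1 * (mu1^2 + s1) + nu2 * (mu2^2 + s2b)) / nu - mu^2
  if (svar <= 0) return(NULL)
  u1 <- nu1 / nu
  u2 <- (mu - mu1) / (sqrt(svar) * sqrt(nu2 / nu1))
  if (u2 <= 0 || u2 >= 1) return(NULL)
  u3 <- s1 * nu1 / ((1 - u2^2) * svar * nu)
  if (u3 <= 0 || u3 >= 1) return(NULL)
  means <- c(params_t1$means[-c(i, j)], mu)
  precisions <- c(params_t1$precisions[-c(i, j)], 1 / svar)
  weights <- c(params_t1$weights[-c(i, j)], nu)
  ord <- order(means)
  params <- mixture_params(means[ord], precisions[ord], weights[ord])
  l <- which(ord == length(means))
  u <- list(u1 = u1, u2 = u2, u3 = u3)
  sp <- rg_split_values(mu, 1 / svar, nu, u1, u2, u3)
  list(params = params, l = l, u = u,
       log_jac_forward = rg_split_log_jac(mu, 1 / svar, nu, u1, u2, u3, sp))
}
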