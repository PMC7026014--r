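make_data <- function(seed = 42, n = 20) {
  set.seed(seed)
  mixture_dataset(c(rnorm(n / 2, -2, 1), rnorm(n / 2, 2, 1)))
}

test_that("mixture containers validate their invariants", {
  expect_error(mixture_params(c(1, 0.5), c(1, 1), c(0.5, 0.5)), "increasing")
  expect_error(mixture_params(c(0, 1), c(-1, 1), c(0.5, 0.5)), "positive")
  expect_error(mixture_params(c(0, 1), c(1, 1), c(0.7, 0.5)), "sum to one")
  d <- make_data()
  pr <- mixture_priors(d)
  expect_equal(pr$mu_mean, mean(d$y))
  expect_equal(pr$mu_sd, diff(range(d$y)))
  expect_equal(pr$tau_rate, 2 * diff(range(d$y))^2 / 100)
})

test_that("the split and merge transformations are mutually inverse", {
  set.seed(7)
  for (r in 1:20) {
    t <- sample(1:4, 1)
    p <- mixture_params(sort(rnorm(t, 0, 3)), rgamma(t, 2, 1), {
      e <- rexp(t); e / sum(e)
    })
    l <- sample(t, 1)
    sp <- split_route(p, l)
    mg <- merge_components(sp$params, sp$children[1], sp$children[2])
    expect_false(is.null(mg))
    expect_equal(mg$params$means, p$means, tolerance = 1e-9)
    expect_equal(mg$params$precisions, p$precisions, tolerance = 1e-9)
    expect_equal(mg$params$weights, p$weights, tolerance = 1e-9)
    expect_equal(mg$l, l)
    expect_equal(unlist(mg$u), unlist(sp$u), tolerance = 1e-9)
    ## the Jacobian evaluated at corresponding points agrees
    expect_equal(mg$log_jac_forward, sp$log_jac_forward, tolerance = 1e-9)
  }
})

test_that("the split Jacobian matches a finite-difference determinant", {
  ## the 6 -> 6 map (mu, tau, nu, u1, u2, u3) -> (mu1, tau1, nu1, mu2, tau2,
  ## nu2) in precision coordinates
  split_vec <- function(x) {
    sp <- tsmc:::rg_split_values(x[1], x[2], x[3], x[4], x[5], x[6])
    c(sp$mu1, sp$tau1, sp$nu1, sp$mu2, sp$tau2, sp$nu2)
  }
  set.seed(8)
  for (r in 1:10) {
    x <- c(rnorm(1), rgamma(1, 2, 1), runif(1, 0.2, 0.9),
           runif(1, 0.1, 0.9), runif(1, 0.1, 0.9), runif(1, 0.1, 0.9))
    J <- matrix(0, 6, 6)
    h <- 1e-6
    for (k in 1:6) {
      e <- numeric(6); e[k] <- h * max(1, abs(x[k]))
      J[, k] <- (split_vec(x + e) - split_vec(x - e)) / (2 * e[k])
    }
    sp <- tsmc:::rg_split_values(x[1], x[2], x[3], x[4], x[5], x[6])
    want <- tsmc:::rg_split_log_jac(x[1], x[2], x[3], x[4], x[5], x[6], sp)
    expect_equal(log(abs(det(J))), want, tolerance = 1e-4)
  }
})

test_that("birth and its inverse are mutually inverse with the stated Jacobian", {
  set.seed(9)
  d <- make_data()
  pr <- mixture_priors(d)
  for (r in 1:10) {
    t <- sample(1:4, 1)
    p <- mixture_params(sort(rnorm(t, 0, 3)), rgamma(t, 2, 1), {
      e <- rexp(t); e / sum(e)
    })
    b <- birth_route(p, priors = pr)
    inv <- birth_inverse(b$params, b$position)
    expect_equal(inv$params$means, p$means, tolerance = 1e-9)
    expect_equal(inv$params$weights, p$weights, tolerance = 1e-9)
    expect_equal(inv$u$nu, b$u$nu, tolerance = 1e-12)
    expect_equal(b$log_jac_forward, (t - 1) * log1p(-b$u$nu))
  }
  ## finite-difference check of the weight-rescaling Jacobian at t = 3:
  ## (nu1, nu2, nustar) -> (nu1 (1-nustar), nu2 (1-nustar), nu3 (1-nustar))
  ## with nu3 = 1 - nu1 - nu2 has |J| = (1 - nustar)^2
  f <- function(x) c(x[1] * (1 - x[3]), x[2] * (1 - x[3]),
                     (1 - x[1] - x[2]) * (1 - x[3]))
  x <- c(0.3, 0.4, 0.25)
  J <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- 1e-7
    J[, k] <- (f(x + e) - f(x - e)) / 2e-7
  }
  expect_equal(log(abs(det(J))), 2 * log1p(-x[3]), tolerance = 1e-6)
})

test_that("the unnormalised posterior integrates to the marginal likelihood", {
  ## with no observations the target is the normalised ordered prior, so the
  ## prior-to-posterior sampler returns exactly log Z = 0 for every t
  d <- make_data()
  pr <- mixture_priors(d, 4)
  set.seed(10)
  for (t in c(1, 3)) expect_equal(smc2_evidence(t, NULL, pr, 50), 0)
})

test_that("log posterior penalises off-support parameters", {
  d <- make_data()
  pr <- mixture_priors(d)
  p_bad <- list(means = c(1, 0), precisions = c(1, 1), weights = c(0.5, 0.5))
  expect_identical(mix_log_posterior(p_bad, d, pr), -Inf)
  p <- mixture_params(c(-1, 1), c(1, 2), c(0.3, 0.7))
  lp <- mix_log_posterior(p, d, pr)
  expect_true(is.finite(lp))
  ## decomposes as ordered prior + likelihood
  want <- sum(dnorm(p$means, pr$mu_mean, pr$mu_sd, log = TRUE)) +
    sum(dgamma(p$precisions, 2, rate = pr$tau_rate, log = TRUE)) +
    lgamma(2) + lfactorial(2) + mix_log_likelihood(p, d)
  expect_equal(lp, want, tolerance = 1e-12)
})

test_that("merges outside the split image are rejected", {
  ## children with wildly unequal variances cannot come from a Beta(1,1) u3
  p <- mixture_params(c(-5, 5), c(100, 100), c(0.5, 0.5))
  ## merging these gives u2 outside (0,1) or u3 outside (0,1) for some configs;
  ## a merge in the wrong mean order must always fail
  expect_null(merge_components(p, 2, 1))
})
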