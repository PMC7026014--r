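make_data <- function(seed = 42, n = 20) {
  set.seed(seed)
  mixture_dataset(c(rnorm(n / 2, -2, 1), rnorm(n / 2, 2, 1)))
}

random_population <- function(P, t, seed = 11) {
  set.seed(seed)
  mu <- t(apply(matrix(rnorm(P * t, 0, 3), P), 1, sort))
  if (t == 1) mu <- matrix(mu, P, 1)
  tau <- matrix(rgamma(P * t, 2, 1), P)
  e <- matrix(rexp(P * t), P)
  mixture_particles(mu, tau, e / rowSums(e))
}

test_that("matrix row utilities agree with their per-row definitions", {
  set.seed(12)
  M <- matrix(rnorm(40), 8)
  ord <- tsmc:::row_order(M)
  for (p in 1:8) expect_identical(ord[p, ], order(M[p, ]))
  G <- tsmc:::row_gather(M, ord)
  for (p in 1:8) expect_identical(G[p, ], sort(M[p, ]))
  l <- sample(5, 8, replace = TRUE)
  D <- tsmc:::drop_col(M, l)
  for (p in 1:8) expect_identical(D[p, ], M[p, -l[p]])
  L <- tsmc:::row_logsumexp(M)
  for (p in 1:8) expect_equal(L[p], log(sum(exp(M[p, ]))), tolerance = 1e-12)
})

test_that("matrix likelihood and target match the scalar definitions", {
  d <- make_data()
  pr <- mixture_priors(d)
  v <- random_population(6, 3)
  ll <- tsmc:::mix_loglik_mat(d$y, v$mu, v$tau, v$nu)
  lt <- tsmc:::mix_log_target_mat(v, d, pr)
  for (p in 1:6) {
    par <- mixture_params(v$mu[p, ], v$tau[p, ], v$nu[p, ])
    expect_equal(ll[p], mix_log_likelihood(par, d), tolerance = 1e-10)
    expect_equal(lt[p], mix_log_posterior(par, d, pr), tolerance = 1e-10)
  }
  ## off-support rows get -Inf
  v$tau[2, 1] <- -1
  expect_identical(tsmc:::mix_log_target_mat(v, d, pr)[2], -Inf)
})

test_that("the likelihood evaluation counter tracks P * N * t", {
  d <- make_data()
  v <- random_population(6, 3)
  reset_eval_counter()
  tsmc:::mix_loglik_mat(d$y, v$mu, v$tau, v$nu)
  expect_identical(get_eval_counter(), 6 * d$n * 3)
})

test_that("vectorised merge contributions match the scalar merge route", {
  d <- make_data()
  pr <- mixture_priors(d)
  v <- random_population(30, 3, seed = 13)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    got <- tsmc:::merge_pair_contrib(v, pair[1], pair[2], d, pr)
    for (p in 1:30) {
      par <- mixture_params(v$mu[p, ], v$tau[p, ], v$nu[p, ])
      mg <- merge_components(par, pair[1], pair[2])
      if (is.null(mg)) {
        expect_identical(got[p], -Inf)
      } else {
        want <- mix_log_posterior(mg$params, d, pr) +
          dbeta(mg$u$u1, 2, 2, log = TRUE) + dbeta(mg$u$u2, 2, 2, log = TRUE) -
          mg$log_jac_forward
        expect_equal(got[p], want, tolerance = 1e-9)
      }
    }
  }
})

test_that("valid-pair counts agree with scalar enumeration", {
  d <- make_data()
  pr <- mixture_priors(d)
  v <- random_population(30, 3, seed = 14)
  cnt <- tsmc:::count_valid_pairs(v, d, pr)
  for (p in 1:30) {
    par <- mixture_params(v$mu[p, ], v$tau[p, ], v$nu[p, ])
    n_ok <- 0L
    for (i in 1:2) for (j in (i + 1):3)
      if (!is.null(merge_components(par, i, j))) n_ok <- n_ok + 1L
    expect_identical(cnt[p], n_ok)
  }
})

test_that("the marginal split proposal sums the per-pair densities", {
  d <- make_data()
  pr <- mixture_priors(d)
  b <- bridge_for_transition(2, "split", "marginal", pr, d)
  v <- random_population(20, 3, seed = 15)
  got <- b$log_phi_from(v)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  per <- sapply(pairs, function(pp) tsmc:::merge_pair_contrib(v, pp[1], pp[2], d, pr))
  want <- apply(per - log(2), 1, function(x) {
    m <- max(x)
    if (!is.finite(m)) -Inf else m + log(sum(exp(x - m)))
  })
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the marginal birth proposal sums over deletion positions", {
  d <- make_data()
  pr <- mixture_priors(d)
  b <- bridge_for_transition(2, "birth", "marginal", pr, d)
  v <- random_population(10, 3, seed = 16)
  got <- b$log_phi_from(v)
  want <- numeric(10)
  for (p in 1:10) {
    par <- mixture_params(v$mu[p, ], v$tau[p, ], v$nu[p, ])
    contrib <- vapply(1:3, function(l) {
      inv <- birth_inverse(par, l)
      mix_log_posterior(inv$params, d, pr) +
        dnorm(inv$u$mu, pr$mu_mean, pr$mu_sd, log = TRUE) +
        dgamma(inv$u$tau, pr$tau_shape, rate = pr$tau_rate, log = TRUE) +
        dbeta(inv$u$nu, 1, 2, log = TRUE) - 1 * log1p(-inv$u$nu)
    }, numeric(1))
    m <- max(contrib)
    want[p] <- m + log(sum(exp(contrib - m)))
  }
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("transformed populations carry consistent bookkeeping", {
  set.seed(17)
  d <- make_data()
  pr <- mixture_priors(d)
  v <- random_population(50, 2, seed = 18)
  bs <- bridge_for_transition(2, "split", "conditional", pr, d)
  v2 <- bs$transform(v)
  expect_identical(dim(v2$mu), c(50L, 3L))
  ## children positions index the two split offspring: their weights merge
  ## back to a weight present in no other column pattern; check means sorted
  expect_true(all(v2$mu[, 1] <= v2$mu[, 2] & v2$mu[, 2] <= v2$mu[, 3]))
  expect_true(all(v2$children >= 1 & v2$children <= 3))
  expect_true(all(v2$children[, 1] < v2$children[, 2]))
  expect_equal(rowSums(v2$nu), rep(1, 50), tolerance = 1e-12)
  bb <- bridge_for_transition(2, "birth", "conditional", pr, d)
  v3 <- bb$transform(v)
  expect_true(all(v3$birth_pos >= 1 & v3$birth_pos <= 3))
  ## removing the born component recovers the original weights
  for (p in c(1, 25, 50)) {
    inv <- birth_inverse(mixture_params(v3$mu[p, ], v3$tau[p, ], v3$nu[p, ]),
                         v3$birth_pos[p])
    expect_equal(inv$params$means, v$mu[p, ], tolerance = 1e-12)
    expect_equal(inv$params$weights, v$nu[p, ], tolerance = 1e-9)
  }
})

test_that("one-component models use the degenerate split label correctly", {
  ## at t = 1 there is a single route and a single valid merge pair, so the
  ## conditional and marginal bridges give identical extended densities
  set.seed(19)
  d <- make_data()
  pr <- mixture_priors(d)
  v <- random_population(40, 1, seed = 20)
  bc <- bridge_for_transition(1, "split", "conditional", pr, d)
  bm <- bridge_for_transition(1, "split", "marginal", pr, d)
  v2 <- bc$transform(v)
  expect_equal(bc$log_phi_from(v2), bm$log_phi_from(v2), tolerance = 1e-10)
  expect_equal(bc$log_phi_to(v2), bm$log_phi_to(v2), tolerance = 1e-10)
})

test_that("the mixture MCMC kernel preserves constraints and moves particles", {
  set.seed(21)
  d <- make_data()
  pr <- mixture_priors(d)
  sys <- smc2_evidence(2, d, pr, 100, return_system = TRUE)
  v <- sys$values
  w <- exp(sys$log_weights - max(sys$log_weights))
  w <- w / sum(w)
  b <- structure(list(
    log_phi_from = function(x) tsmc:::mix_log_prior_mat(x$mu, x$tau, x$nu, pr),
    log_phi_to = function(x) tsmc:::mix_log_target_mat(x, d, pr)),
    class = "tsmc_bridge")
  out <- mixture_mcmc_kernel(v, 1, b, w)
  expect_gt(out$accept, 0.05)
  expect_true(all(out$values$mu[, 1] < out$values$mu[, 2]))
  expect_true(all(out$values$tau > 0))
  expect_equal(rowSums(out$values$nu), rep(1, 100), tolerance = 1e-9)
  expect_false(all(out$values$mu == v$mu))
})
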