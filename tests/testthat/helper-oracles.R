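## Independent oracles used by the test suite. These deliberately avoid the
## package's own numerical machinery: quadrature on dense grids, prior
## importance sampling, and brute-force enumeration.

## ---------------------------------------------------------------------------
## mixture model oracles

## One-component evidence by dense 2-D quadrature over (mu, tau).
quad_mixture_z1 <- function(y, priors, n_mu = 600, n_tau = 600) {
  gmu <- seq(priors$mu_mean - 8 * priors$mu_sd, priors$mu_mean + 8 * priors$mu_sd,
             length.out = n_mu)
  gtau <- exp(seq(log(1e-5), log(10), length.out = n_tau))
  f <- function(mu, tau)
    exp(sum(dnorm(y, mu, 1 / sqrt(tau), log = TRUE)) +
        dnorm(mu, priors$mu_mean, priors$mu_sd, log = TRUE) +
        dgamma(tau, priors$tau_shape, rate = priors$tau_rate, log = TRUE))
  vals <- matrix(0, n_mu, n_tau)
  for (i in seq_len(n_mu)) for (j in seq_len(n_tau))
    vals[i, j] <- f(gmu[i], gtau[j])
  dtau <- diff(gtau)
  inner <- as.vector((vals[, -1] + vals[, -n_tau]) %*% dtau) / 2
  log(sum(inner) * (gmu[2] - gmu[1]))
}

## Two-component evidence by prior importance sampling (the ordered-prior
## normalisation makes Z_2 = E_{unordered prior}[likelihood] directly).
is_mixture_z2 <- function(y, priors, n = 4e5) {
  mu1 <- rnorm(n, priors$mu_mean, priors$mu_sd)
  mu2 <- rnorm(n, priors$mu_mean, priors$mu_sd)
  t1 <- rgamma(n, priors$tau_shape, rate = priors$tau_rate)
  t2 <- rgamma(n, priors$tau_shape, rate = priors$tau_rate)
  w1 <- runif(n)
  ll <- numeric(n)
  for (i in seq_along(y))
    ll <- ll + log(w1 * dnorm(y[i], mu1, 1 / sqrt(t1)) +
                   (1 - w1) * dnorm(y[i], mu2, 1 / sqrt(t2)))
  m <- max(ll)
  r <- exp(ll - m)
  list(log_z = m + log(mean(r)), rel_se = sd(r) / mean(r) / sqrt(n))
}

## ---------------------------------------------------------------------------
## Jukes-Cantor brute force: likelihood by enumerating internal node states.

jc_transition <- function(d) {
  e <- exp(-4 * d / 3)
  matrix(0.25 - 0.25 * e, 4, 4) + diag(4) * e
}

jc_enum_loglik <- function(parent, heights, nleaf, codes, theta) {
  m <- length(parent)
  internals <- seq.int(nleaf + 1L, m)
  n_int <- length(internals)
  edges <- which(parent != 0L)
  pmats <- lapply(edges, function(v)
    jc_transition(0.5 * theta * (heights[parent[v]] - heights[v])))
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  ll <- 0
  for (s in seq_len(ncol(codes))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      b <- integer(m)
      b[seq_len(nleaf)] <- codes[, s]
      b[internals] <- grid[g, ]
      p <- 0.25
      for (ei in seq_along(edges)) {
        v <- edges[ei]
        p <- p * pmats[[ei]][b[parent[v]], b[v]]
      }
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

## ---------------------------------------------------------------------------
## 3-leaf coalescent evidence by tensor-grid quadrature over the 3 labelled
## topologies x (first coalescence h1, root h2 > h1) x theta.

coal3_quadrature <- function(aln, theta_shape = 1, theta_rate = 5,
                             n_h1 = 200, n_h2 = 150, n_th = 120,
                             h1_max = 6, h2_extra = 9, th_max = 3) {
  codes <- aln$codes
  key <- apply(codes, 2, paste, collapse = ".")
  first <- !duplicated(key)
  patt <- codes[, first, drop = FALSE]
  counts <- as.numeric(table(factor(key, levels = key[first])))
  g1 <- seq(1e-4, h1_max, length.out = n_h1)
  dg2 <- seq(1e-4, h2_extra, length.out = n_h2)
  gth <- exp(seq(log(1e-4), log(th_max), length.out = n_th))
  H1 <- rep(g1, times = n_h2)
  DG <- rep(dg2, each = n_h1)
  w1 <- rep(c(g1[1], diff(g1)), times = n_h2)
  w2 <- rep(c(dg2[1], diff(dg2)), each = n_h1)
  ps <- function(e) 0.25 + 0.75 * e
  pd <- function(e) 0.25 - 0.25 * e
  total <- 0
  for (ti in seq_len(n_th)) {
    th <- gth[ti]
    wth <- if (ti == 1) gth[1] else gth[ti] - gth[ti - 1]
    e1 <- exp(-2 * th * H1 / 3)       # leaf -> cherry node (d = th h1 / 2)
    e2 <- exp(-2 * th * DG / 3)       # cherry node -> root
    e3 <- exp(-2 * th * (H1 + DG) / 3)  # outgroup leaf -> root
    for (tp in list(c(1, 2), c(1, 3), c(2, 3))) {
      i <- tp[1]; j <- tp[2]; k <- setdiff(1:3, tp)
      ll <- 0
      for (s in seq_len(ncol(patt))) {
        a <- patt[i, s]; b <- patt[j, s]; cc <- patt[k, s]
        pr <- 0
        for (u in 1:4) for (r in 1:4) {
          pr <- pr + 0.25 *
            (if (u == a) ps(e1) else pd(e1)) *
            (if (u == b) ps(e1) else pd(e1)) *
            (if (r == u) ps(e2) else pd(e2)) *
            (if (r == cc) ps(e3) else pd(e3))
        }
        ll <- ll + counts[s] * log(pr)
      }
      integrand <- exp(ll - 3 * H1 - DG +
                       dgamma(th, theta_shape, rate = theta_rate, log = TRUE))
      total <- total + wth * sum(integrand * w1 * w2)
    }
  }
  log(total)
}

## ---------------------------------------------------------------------------
## small utilities

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## canonical representation of a genealogy: each internal node as
## "sorted leafset @ height" (for exact tree comparisons up to node indexing)
clade_signature <- function(state, digits = 9) {
  n <- state$n_leaves
  m <- length(state$parent)
  leafsets <- vector("list", m)
  for (i in seq_len(n)) leafsets[[i]] <- i
  ord <- order(state$heights)
  for (v in ord) {
    if (v <= n) next
    kids <- which(state$parent == v)
    leafsets[[v]] <- sort(unlist(leafsets[kids]))
  }
  sig <- vapply(seq.int(n + 1L, m), function(v)
    paste0(paste(leafsets[[v]], collapse = ","), "@",
           formatC(state$heights[v], digits = digits, format = "g")),
    character(1))
  sort(sig)
}

topology_signature <- function(state) {
  sort(sub("@.*$", "", clade_signature(state)))
}

weighted_var <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sum(w * (x - m)^2)
}
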