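## Synthetic-data generators: coalescent genealogies, Jukes-Cantor sequence
## evolution along them, and Gaussian mixture draws.

#' Simulate a Kingman coalescent genealogy
#'
#' While `a` lineages remain, waits an `Exp(choose(a, 2))` time and merges a
#' uniformly chosen pair. Leaves are nodes `1..n`; coalescences `n+1..2n-1`
#' in time order (so heights increase with node index).
#'
#' @param n_leaves number of leaves.
#' @param theta scaled mutation rate to attach to the state.
#' @return a [coalescent_state()].
#' @export
simulate_coalescent_tree <- function(n_leaves, theta = 1) {
  n <- as.integer(n_leaves)
  stopifnot(n >= 2)
  m <- 2L * n - 1L
  parent <- integer(m)
  heights <- numeric(m)
  active <- seq_len(n)
  time <- 0
  for (k in seq_len(n - 1L)) {
    a <- length(active)
    time <- time + rexp(1, choose(a, 2))
    pair <- sample(active, 2L)
    node <- n + k
    parent[pair] <- node
    heights[node] <- time
    active <- c(setdiff(active, pair), node)
  }
  coalescent_state(parent, heights, theta, n)
}

#' Evolve sequences along a genealogy under the Jukes-Cantor model
#'
#' Draws the root sequence uniformly over bases and mutates down each branch:
#' a branch of duration `l` carries `d = (theta/2) * l` expected
#' substitutions per site, under which each site is independently redrawn
#' uniformly with probability `1 - exp(-4d/3)` (the exact Jukes-Cantor
#' transition kernel).
#'
#' @param state a [coalescent_state()] (its `theta` sets the rate).
#' @param n_sites number of sites to simulate.
#' @param labels sequence names (default `t1..tn`).
#' @return a [dna_alignment()] with one row per leaf, in leaf order.
#' @export
evolve_sequences <- function(state, n_sites, labels = NULL) {
  n <- state$n_leaves
  m <- length(state$parent)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  root <- which(state$parent == 0L)
  seqs <- matrix(0L, m, n_sites)
  seqs[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  ## visit children after parents: decreasing height works for any indexing
  ord <- order(state$heights, decreasing = TRUE)
  for (v in ord) {
    if (v == root) next
    p <- state$parent[v]
    d <- 0.5 * state$theta * (state$heights[p] - state$heights[v])
    redraw <- runif(n_sites) > exp(-4 * d / 3)
    seqs[v, ] <- ifelse(redraw, sample.int(4L, n_sites, replace = TRUE), seqs[p, ])
  }
  dna_alignment(matrix(DNA_LEVELS[seqs[seq_len(n), , drop = FALSE]], nrow = n),
                labels = labels)
}

#' Simulate from a Gaussian mixture
#'
#' @param params a [mixture_params()].
#' @param n number of observations.
#' @return a [mixture_dataset()].
#' @export
simulate_mixture_data <- function(params, n) {
  comp <- sample.int(length(params$weights), n, replace = TRUE,
                     prob = params$weights)
  mixture_dataset(rnorm(n, params$means[comp],
                        1 / sqrt(params$precisions[comp])))
}
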