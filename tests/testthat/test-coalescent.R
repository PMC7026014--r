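random_codes <- function(n, L, seed) {
  set.seed(seed)
  matrix(sample(1:4, n * L, replace = TRUE), n, L)
}

aln_from_codes <- function(codes) {
  dna_alignment(matrix(DNA_LEVELS[codes], nrow(codes)))
}

## a fixed 4-leaf clock tree: ((1,2)@0.3, 3)@0.7 with 4 joining at 1.2
tree4 <- function(theta = 0.1) {
  coalescent_state(parent = c(5, 5, 6, 7, 6, 7, 0),
                   heights = c(0, 0, 0, 0, 0.3, 0.7, 1.2),
                   theta = theta, n_leaves = 4)
}

test_that("coalescent states validate their invariants", {
  expect_error(coalescent_state(c(3, 3, 0), c(0, 0.1, 1), 1, 2),
               "height 0")
  expect_error(coalescent_state(c(3, 3, 0), c(0, 0, -1), 1, 2),
               "exceed")
  expect_error(coalescent_state(c(3, 3, 1), c(0, 0, 1), 1, 2), "root")
  expect_error(coalescent_state(c(3, 3, 0), c(0, 0, 1), -1, 2), "positive")
  expect_error(coalescent_state(c(3, 3), c(0, 0), 1, 2), "2n-1")
})

test_that("the genealogy prior matches the interval formula", {
  st <- tree4()
  ## 4 lineages on [0, 0.3), 3 on [0.3, 0.7), 2 on [0.7, 1.2)
  want <- -(6 * 0.3 + 3 * 0.4 + 1 * 0.5)
  expect_equal(coalescent_log_prior(st), want, tolerance = 1e-12)
  ## a parent below its child has zero prior density
  st_bad <- st
  st_bad$heights[6] <- 0.2
  expect_identical(tsmc:::.coal_log_prior_cpp(st_bad$parent - 1L,
                                              st_bad$heights, 4L), -Inf)
})

test_that("pruning matches brute-force enumeration over internal states", {
  codes <- random_codes(4, 30, seed = 31)
  aln <- aln_from_codes(codes)
  for (theta in c(0.05, 0.5, 2)) {
    st <- tree4(theta)
    got <- jc_log_likelihood(st, aln)
    want <- jc_enum_loglik(st$parent, st$heights, 4, codes, theta)
    expect_lt(abs(got - want), 1e-10)
  }
  ## single-sequence likelihood is the uniform root distribution
  st1 <- coalescent_state(0L, 0, 0.3, 1L)
  a1 <- aln_from_codes(codes[1, , drop = FALSE])
  expect_equal(jc_log_likelihood(st1, a1), 30 * log(0.25), tolerance = 1e-12)
})

test_that("the likelihood is invariant to re-rooting the genealogy", {
  codes <- random_codes(4, 40, seed = 32)
  cp <- list(patt = codes - 1L, counts = rep(1, 40))
  theta <- 0.4
  st <- tree4(theta)
  base <- tsmc:::.jc_loglik_cpp(st$parent - 1L, st$heights, 4L,
                                cp$patt, cp$counts, theta)
  ## the same unrooted tree re-rooted on the (5,6) edge, 0.1 + 0.3 split;
  ## the old root becomes a straight-through point absorbed into the 4-6
  ## edge (1.2 + 0.5). Heights just encode branch durations here.
  parent2 <- c(5L, 5L, 6L, 6L, 7L, 7L, 0L)
  heights2 <- c(1.6, 1.6, 1.0, 0, 1.9, 1.7, 2.0)
  got <- tsmc:::.jc_loglik_cpp(parent2 - 1L, heights2, 4L,
                               cp$patt, cp$counts, theta)
  expect_lt(abs(got - base), 1e-10)
  ## shifting every height leaves the likelihood unchanged too
  got2 <- tsmc:::.jc_loglik_cpp(st$parent - 1L, st$heights + 3.7, 4L,
                                cp$patt, cp$counts, theta)
  expect_lt(abs(got2 - base), 1e-10)
})

test_that("leaf addition and removal are mutually inverse", {
  set.seed(33)
  for (r in 1:20) {
    st <- simulate_coalescent_tree(sample(3:7, 1), theta = 0.3)
    lineage <- sample(st$n_leaves, 1)
    height <- rexp(1, 1)
    st2 <- add_leaf(st, lineage, height)
    expect_identical(st2$n_leaves, st$n_leaves + 1L)
    ## the new leaf's parent sits at the requested height
    expect_equal(st2$heights[st2$parent[st$n_leaves + 1L]], height)
    back <- remove_leaf(st2)
    expect_identical(clade_signature(back), clade_signature(st))
    expect_equal(back$heights, st$heights, tolerance = 1e-12)
    expect_identical(back$parent, st$parent)
  }
})

test_that("inverse-image lineages are the sibling-subtree leaves", {
  st <- coalescent_state(c(4, 4, 5, 5, 0), c(0, 0, 0, 0.4, 1.0), 0.3, 3)
  ## ((1,2)@0.4, 3)@1.0; attach leaf 4 at three depths on lineage of 1
  low <- add_leaf(st, 1, 0.2)
  expect_identical(inverse_image_lineages(low), 1L)
  mid <- add_leaf(st, 1, 0.7)
  expect_identical(inverse_image_lineages(mid), c(1L, 2L))
  high <- add_leaf(st, 1, 1.5)
  expect_identical(inverse_image_lineages(high), c(1L, 2L, 3L))
})

test_that("lineage weights follow the annealed mismatch geometric form", {
  w <- lineage_weights(c(0L, 2L), n_sites = 100, theta = 0.05)
  ## r = N theta / (t + N theta) = 5/7; weights prop to (1, (5/7)^2)
  expect_equal(w, c(49, 25) / 74, tolerance = 1e-12)
  ## power 0 is uniform regardless of mismatches
  expect_equal(lineage_weights(c(3L, 9L, 1L), 100, 0.05, power = 0),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(lineage_weights(c(5L, 1L, 0L, 7L), 200, 0.1)), 1,
               tolerance = 1e-12)
})

test_that("height proposals are normalised and centred on the likelihood mode", {
  hp <- height_proposal(mismatch = 8, n_sites = 100, theta = 0.05)
  expect_identical(hp$kind, "lognormal")
  z <- integrate(function(h) exp(hp$log_density(h)), 0, Inf)$value
  expect_equal(z, 1, tolerance = 1e-6)
  ## the fitted meanlog maximises pairwise JC loglik + log-height Jacobian
  g <- function(x) {
    e <- exp(-4 * 0.05 * exp(x) / 3)
    8 * log(0.25 - 0.25 * e) + 92 * log(0.25 + 0.75 * e) + x
  }
  eps <- 1e-3
  expect_lt(abs((g(hp$meanlog + eps) - g(hp$meanlog - eps)) / (2 * eps)), 1e-3)
  ## identical sequences fall back to Exp(1)
  hp0 <- height_proposal(0, 100, 0.05)
  expect_identical(hp0$kind, "exp1")
  expect_equal(hp0$log_density(c(0.5, 2)), c(-0.5, -2))
  expect_identical(hp0$log_density(-1), -Inf)
  ## sampling respects the declared density
  set.seed(34)
  hs <- hp$sample(20000)
  expect_equal(mean(log(hs)), hp$meanlog, tolerance = 4 * hp$sdlog / sqrt(20000) + 1e-3)
})

test_that("the bridge start density replays the proposal over candidate lineages", {
  set.seed(35)
  base <- simulate_coalescent_tree(4, theta = 0.2)
  aln <- evolve_sequences(base, n_sites = 60)
  b <- leaf_addition_bridge(aln, t = 3, theta_hat = 0.2)
  for (r in 1:20) {
    st <- simulate_coalescent_tree(3, theta = 0.2)
    st$theta <- rgamma(1, 2, 4)
    lineage <- sample(3, 1)
    h <- rexp(1)
    st2 <- add_leaf(st, lineage, h)
    got <- b$log_phi_from(list(st2))
    ## replay: which lineages reproduce st2 when the new leaf re-attaches?
    sig <- clade_signature(st2)
    qs <- vapply(1:3, function(s) {
      cand <- add_leaf(st, s, h)
      if (identical(clade_signature(cand), sig))
        log(b$chi_g[s]) + b$height_proposals[[s]]$log_density(h)
      else -Inf
    }, numeric(1))
    want <- coalescent_log_prior(st) +
      jc_log_likelihood(st, subset_alignment(aln, 1:3)) +
      dgamma(st$theta, 1, rate = 5, log = TRUE) + lse(qs)
    expect_equal(got, want, tolerance = 1e-9)
    ## and the compiled single-state entry point agrees
    direct <- tsmc:::.coal_proposal_logdens_cpp(
      st2$parent - 1L, st2$heights, 3L, 4L, b$bridge_data$log_chi_g,
      b$bridge_data$lap_mean, b$bridge_data$lap_sd, b$bridge_data$use_lap)
    expect_equal(direct, lse(qs), tolerance = 1e-9)
  }
})

test_that("the bridge end density is the full posterior kernel", {
  set.seed(36)
  base <- simulate_coalescent_tree(4, theta = 0.2)
  aln <- evolve_sequences(base, n_sites = 60)
  b <- leaf_addition_bridge(aln, t = 3, theta_hat = 0.2)
  st <- simulate_coalescent_tree(4, theta = 0.2)
  st$theta <- 0.17
  got <- b$log_phi_to(list(st))
  want <- coalescent_log_prior(st) + jc_log_likelihood(st, aln) +
    dgamma(0.17, 1, rate = 5, log = TRUE)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("the MCMC sweep preserves genealogy validity and moves the state", {
  set.seed(37)
  base <- simulate_coalescent_tree(5, theta = 0.2)
  aln <- evolve_sequences(base, n_sites = 50)
  b <- leaf_addition_bridge(aln, t = 4, theta_hat = 0.2)
  kernel <- coalescent_mcmc_kernel(topology_moves = TRUE, n_topo = 2)
  values <- lapply(1:30, function(i) {
    st <- simulate_coalescent_tree(4, 0.2)
    st$theta <- rgamma(1, 1, 5)
    add_leaf(st, sample(4, 1), rexp(1))
  })
  out <- kernel(values, 0.5, b, rep(1 / 30, 30))
  expect_gt(out$accept, 0.02)
  moved <- FALSE
  for (i in 1:30) {
    st <- out$values[[i]]
    expect_s3_class(st, "coalescent_state")  # constructor re-validates
    if (!identical(clade_signature(st), clade_signature(values[[i]])) ||
        st$theta != values[[i]]$theta) moved <- TRUE
  }
  expect_true(moved)
})

test_that("sequence orderings follow the greedy mismatch rules", {
  aln <- dna_alignment(c("aaaaaaaaaa",
                         "caaaaaaaaa",
                         "agggggaaaa"))
  D <- tsmc:::pairwise_mismatches(aln)
  expect_identical(D[1, 2], 1L)
  expect_identical(D[1, 3], 5L)
  expect_identical(D[2, 3], 6L)
  expect_identical(sequence_ordering(aln, "nearest"), c(1L, 2L, 3L))
  expect_identical(sequence_ordering(aln, "furthest"), c(2L, 3L, 1L))
  expect_identical(sequence_ordering(aln, "given"), 1:3)
})

test_that("majority consensus keeps exactly the >1/2-supported clades", {
  stA <- coalescent_state(c(5, 5, 6, 6, 7, 7, 0),
                          c(0, 0, 0, 0, 0.5, 0.6, 1), 0.1, 4)  # ((1,2),(3,4))
  stC <- coalescent_state(c(5, 6, 5, 6, 7, 7, 0),
                          c(0, 0, 0, 0, 0.5, 0.6, 1), 0.1, 4)  # ((1,3),(2,4))
  cons <- majority_consensus(list(stA, stA, stC), weights = c(0.5, 0.3, 0.2))
  supports <- attr(cons, "supports")
  expect_setequal(names(supports), c("1,2", "3,4", "1,2,3,4"))
  expect_equal(unname(supports["1,2"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(supports["3,4"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(supports["1,2,3,4"]), 1, tolerance = 1e-12)
  expect_identical(cons$Nnode, 3L)
  ## unanimous input reproduces the full topology
  cons2 <- majority_consensus(list(stA, stA))
  expect_setequal(names(attr(cons2, "supports")), c("1,2", "3,4", "1,2,3,4"))
})

test_that("state/phylo conversions round trip", {
  set.seed(38)
  for (r in 1:10) {
    st <- simulate_coalescent_tree(sample(2:8, 1), theta = 0.3)
    phy <- state_to_phylo(st)
    expect_true(ape::is.binary(phy))
    back <- phylo_to_state(phy, st$theta)
    expect_identical(clade_signature(back), clade_signature(st))
  }
  expect_error(phylo_to_state(ape::read.tree(text = "(t1:1,t2:2);"), 1),
               "ultrametric")
})

test_that("online inference returns a coherent fit on a small alignment", {
  set.seed(39)
  base <- simulate_coalescent_tree(3, theta = 0.1)
  aln <- evolve_sequences(base, n_sites = 80)
  fit <- tsmc_coalescent(aln, n_particles = 60, keep_history = TRUE)
  expect_s3_class(fit, "tsmc_coalescent_fit")
  expect_length(fit$log_evidence_path, 3)
  expect_equal(fit$log_evidence_path[1], 80 * log(0.25))
  expect_identical(fit$log_evidence, fit$log_evidence_path[3])
  expect_true(is.finite(fit$log_evidence))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$theta > 0))
  expect_setequal(fit$order, 1:3)
  expect_length(fit$history, 2)
  expect_s3_class(fit$history[[2]]$values[[1]], "coalescent_state")
  ## the report tracks complete annealing for each addition
  expect_true(all(fit$reports$gamma <= 1))
  expect_equal(max(fit$reports$gamma), 1)
})
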