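test_that("ESS matches its closed form on simple weight vectors", {
  expect_equal(ess(rep(0.1, 10)), 10)
  expect_equal(ess(c(1, 0, 0, 0)), 1)
  expect_equal(ess(c(0.5, 0.5, 0, 0)), 2)
  expect_error(ess(c(NA, 0.5)), "invalid weights")
  expect_error(ess(c(0, 0, 0)), "invalid weights")
})

test_that("CESS matches hand-evaluated values and detects bad input", {
  ## constant increments leave the CESS at P for any normalised weights
  w <- c(0.7, 0.1, 0.15, 0.05)
  expect_equal(cess(w, rep(3.2, 4)), 4)
  ## hand evaluations: P (sum w omega)^2 / sum w omega^2
  expect_equal(cess(c(0.5, 0.5), c(1, 0)), 1)
  expect_equal(cess(rep(0.25, 4), c(1, 1, 1, 0)), 3)
  ## log-domain form agrees with the linear form
  om <- c(0.2, 1.7, 0.9, 0.4)
  expect_equal(cess(w, log(om), log = TRUE), cess(w, om), tolerance = 1e-12)
  expect_error(cess(w, rep(0, 4)), "invalid increments")
  expect_error(cess(w, c(1, NA, 1, 1)), "invalid increments")
})

test_that("adapt_gamma places the CESS at the target within tolerance", {
  set.seed(1)
  P <- 500
  lt_minus_lf <- rnorm(P, 0, 3)
  w <- rep(1 / P, P)
  cfg <- anneal_config(cess_fraction = 0.9)
  g <- adapt_gamma(w, function(g) g * lt_minus_lf, 0, cfg)
  expect_gt(g, 0)
  expect_lt(g, 1)
  realised <- cess(w, g * lt_minus_lf, log = TRUE)
  expect_lt(abs(realised - 0.9 * P), cfg$cess_tol * P + 1e-8)
  ## a grid search over gamma agrees with the bisection
  grid <- seq(1e-4, 1, length.out = 20000)
  cg <- vapply(grid, function(gg) cess(w, gg * lt_minus_lf, log = TRUE), numeric(1))
  g_grid <- grid[which.min(abs(cg - 0.9 * P))]
  ## agreement up to the grid resolution plus the bisection's CESS tolerance
  expect_equal(g, g_grid, tolerance = 5e-3)
})

test_that("adapt_gamma returns 1 when even the full step keeps CESS high", {
  P <- 100
  w <- rep(1 / P, P)
  expect_identical(adapt_gamma(w, function(g) rep(g * 0.01, P), 0,
                               anneal_config()), 1)
})

test_that("geometric reweighting accumulates the evidence increment", {
  sys <- particle_system(1:4, 4)
  lf <- c(0, 0, 0, 0)
  lt <- log(c(2, 2, 2, 2))
  sys <- reweight_geometric(sys, lf, lt, 0, 0.5)
  sys <- reweight_geometric(sys, lf, lt, 0.5, 1)
  expect_equal(log_evidence(sys), log(2), tolerance = 1e-12)
  expect_length(sys$log_evidence_increments, 2)
  expect_equal(sys$anneal_fraction, 1)
})

test_that("stratified resampling has the right expected copy counts", {
  w <- c(0.5, 0.3, 0.15, 0.05)
  ## hard bound: stratified counts deviate from P w by less than 2
  set.seed(2)
  for (r in 1:50) {
    idx <- stratified_resample_indices(w, 100)
    counts <- tabulate(idx, 4)
    expect_true(all(abs(counts - 100 * w) < 2))
  }
  ## statistical: mean counts over many replicates near P w
  set.seed(3)
  counts <- rowMeans(replicate(2000, tabulate(stratified_resample_indices(w, 100), 4)))
  expect_lt(max(abs(counts - 100 * w)), 0.05)
})

test_that("particle degeneracy raises a classed numerical error", {
  sys <- particle_system(1:3, 3, log_weights = rep(-Inf, 3))
  b <- identity_bridge(function(v) rep(0, 3), function(v) rep(0, 3))
  expect_error(run_bridge(sys, b), class = "tsmc_numerical_error")
})

test_that("run_bridge recovers a known Gaussian normalising-constant ratio", {
  set.seed(4)
  lf <- function(v) dnorm(v, log = TRUE)
  lt <- function(v) log(2) + dnorm(v, 0, 2, log = TRUE)
  sys <- particle_system(rnorm(400), 400)
  sys <- run_bridge(sys, identity_bridge(lf, lt), rw_kernel_numeric(),
                    anneal_config(cess_fraction = 0.95))
  expect_equal(log_evidence(sys), log(2), tolerance = 0.15)
  rep <- attr(sys, "report")
  expect_true(all(diff(rep$gamma) > 0))
  expect_equal(rep$gamma[nrow(rep)], 1)
})

test_that("a frozen schedule is honoured verbatim and validated", {
  lf <- function(v) dnorm(v, log = TRUE)
  lt <- function(v) log(2) + dnorm(v, 0, 2, log = TRUE)
  b <- identity_bridge(lf, lt)
  set.seed(7)
  sys <- particle_system(rnorm(100), 100)
  sched <- c(0.25, 0.6, 1)
  out <- run_bridge(sys, b, rw_kernel_numeric(), anneal_config(), schedule = sched)
  expect_equal(attr(out, "report")$gamma, sched)
  expect_error(run_bridge(sys, b, schedule = c(0.5, 0.4, 1)), "increasing")
  expect_error(run_bridge(sys, b, schedule = c(0.5, 0.9)), "end at 1")
})
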