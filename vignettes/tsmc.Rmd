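---
title: "Transformation SMC: evidence estimation across models of changing dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformation SMC: evidence estimation across models of changing dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(tsmc)
```

## The method

`tsmc` implements SMC samplers whose particle population is moved through a
*sequence of posteriors of changing dimension*. A move from model $t$ (target
$\pi_t$ on $\Theta_t$) to model $t+1$ (target $\pi_{t+1}$ on a larger space
$\Theta_{t+1}$) is made in two stages:

1. **Transformation.** Each particle $\theta$ draws auxiliary variables $u$
   and possibly a discrete *route* $\ell$ (one of several alternative maps,
   with prior masses $\rho_\ell$), and is pushed deterministically to
   $\theta' = g_\ell(\theta, u)$. The implied proposal density on
   $\Theta_{t+1}$ is
   $\varphi(\theta') = \pi_t(\theta)\,\psi(u)\,|J_{g_\ell}|^{-1}$
   (conditionally on the drawn route) or the $\rho$-weighted sum over all
   routes whose inverse image exists (the *marginalised* form, which
   Rao-Blackwellises the route and never increases the weight variance).
2. **Annealing.** The population is annealed geometrically from $\varphi$ to
   $\pi_{t+1}$: intermediate targets $\varphi^{1-\gamma}\pi_{t+1}^{\gamma}$,
   with each step $\gamma_{k} \to \gamma_{k+1}$ placed adaptively so that the
   *conditional effective sample size* (CESS) of the incremental weights
   equals a fixed fraction $\beta$ of the population size $P$; the step is
   found by bisection. Resampling (stratified) triggers when the ESS drops
   below $\alpha P$, and an invariant MCMC kernel rejuvenates the population
   after each accepted step.

The product of the weighted-mean incremental weights over all steps and all
model moves is an unbiased estimator of the ratio of normalising constants,
so a single run returns the evidence of every model visited — this is what
makes the sampler useful for Bayesian model comparison and for *online*
inference where data (and parameters) arrive incrementally.

## Application 1: Gaussian mixture model comparison

`tsmc_mixture()` compares univariate Gaussian mixtures with $1, \dots, T$
components (ordered means, Gamma precisions, Dirichlet weights; data-driven
priors follow standard weakly-informative choices based on the data range).
Two transformations from $t$ to $t+1$ components are provided:

* `move = "split"`: a moment-matching split of one existing component into
  two (auxiliary Beta(2,2), Beta(2,2), Uniform variables), with the route
  prior uniform over components whose split respects the mean ordering;
* `move = "birth"`: insertion of a fresh component drawn from its prior,
  with weight renormalisation.

`mode = "marginal"` (default) uses the Rao-Blackwellised proposal density;
`mode = "conditional"` scores only the route actually taken. Both are exact;
the marginal form has lower-variance weights at the cost of evaluating every
route's inverse. `smc2_evidence()` provides the standard within-model
prior-to-posterior annealing estimate of each evidence separately, as an
independent benchmark.

```{r mixture, eval = FALSE}
y <- c(rnorm(10, -2), rnorm(10, 2))
fit <- tsmc_mixture(mixture_dataset(y), max_components = 3,
                    move = "split", mode = "marginal", n_particles = 500)
fit$log_evidence        # log Z_1, Z_2, Z_3 from one run
```

## Application 2: online coalescent inference from DNA

`tsmc_coalescent()` infers a genealogy (a rooted binary tree with coalescence
heights, Kingman labelled-history prior) and the scaled mutation rate
$\theta$ (Gamma prior) from a DNA alignment under the Jukes–Cantor model,
adding one sequence at a time. The transformation attaches the new leaf to a
lineage $s$ at height $h$:

* the lineage is drawn with probability proportional to
  $r^{\,\text{power}\cdot M_s}$ where $M_s$ counts mismatches between the new
  sequence and sequence $s$ and $r = N\hat\theta/(t + N\hat\theta)$ — i.e.
  SNP-guided, favouring genetically close lineages;
* the height is drawn from a log-normal whose parameters come from a Laplace
  approximation to the single-site attachment likelihood (falling back to
  Exp(1), the prior coalescence rate scale, when the approximation is
  degenerate).

The proposal density is marginalised over every lineage whose attachment
reproduces the same genealogy, computed in C++ together with the pruning
likelihood. The MCMC kernel mixes $\theta$ updates, height updates and local
topology moves on the sibling-subtree neighbourhood.

```{r coalescent, eval = FALSE}
tree <- simulate_coalescent_tree(8, theta = 0.05)
aln  <- evolve_sequences(tree, 500)
fit  <- tsmc_coalescent(aln, n_particles = 300)
fit$log_evidence                       # evidence of the full alignment
sum(fit$weights * fit$theta)           # posterior mean mutation rate
majority_consensus(fit$system$values, fit$weights)
```

## Defaults and why

* `cess_fraction` ($\beta$): 0.99 for mixtures, 0.95 for the coalescent.
  Higher $\beta$ gives more, smaller annealing steps; tree targets are
  cheaper per evaluation, so a coarser schedule is the better trade.
* `resample_fraction` ($\alpha$) = 0.5: the conventional ESS/2 rule.
* `mcmc_iters_per_distribution` = 2: enough rejuvenation when bridges
  overlap well. Poorly-overlapping transformations (notably the mixture
  `birth` move on well-separated data) need more sweeps and particles for
  the adaptive schedule's finite-$P$ bias to vanish — the acceptance tests
  run that variant at $P = 150$ with 8 sweeps.
* Sequences are added in a greedy nearest-by-Hamming-distance order
  (`ordering = "nearest"`), which keeps early attachment posteriors
  concentrated.
* $\hat\theta$ used by the lineage and height proposals is the current
  weighted posterior mean of $\theta$, so proposals adapt as data accrue;
  this only affects efficiency, not correctness, because the proposal
  density is computed with the same $\hat\theta$.

## Numerical choices

* All weight arithmetic is in log space with `logsumexp`; dead particles
  ($-\infty$ both sides) are handled explicitly.
* CESS bisection stops at $|{\rm CESS} - \beta P| \le 10^{-3} P$ with a
  minimum step of $10^{-6}$, and the reported per-step realised CESS is part
  of the returned diagnostics (`attr(system, "report")`, `fit$reports`).
* The conditional route density includes the route prior-mass correction for
  routes whose labelling changes under the ordering constraint (after a
  split, sorting the means can relabel which component "was split").
* Jacobians are computed analytically (the split works in precision
  coordinates); unit tests check them against finite differences.
* The Jukes–Cantor pruning likelihood, the marginalised attachment density
  and the MCMC sweep run in C++ (Rcpp); likelihoods operate on compressed
  site patterns.

## Generator scope and problem sizes

The simulators (`simulate_coalescent_tree`, `evolve_sequences`,
`simulate_mixture_data`) are the intended data generators: Kingman
coalescent genealogies, Jukes–Cantor evolution with uniform root bases, and
i.i.d. Gaussian-mixture draws. The package is tuned for small-to-moderate
problems on one core: mixtures with up to ~8 components and a few hundred
observations; alignments of up to ~10–20 sequences and a few thousand sites
with a few hundred particles (an 8-sequence, 500-site run at $P = 300$ takes
on the order of 10 seconds).

## RNG

Everything uses R's global RNG stream (`set.seed()` gives exact
reproducibility, including inside the C++ kernels, which draw through R's
API). The command-line runners (`run_mixture`, `run_coalescent`,
`exec/tsmc`) take an explicit `seed` and write byte-identical artefacts when
rerun with the same seed.

## Limitations

* Transformations only *increase* dimension (model moves $t \to t+1$);
  evidence for every visited model comes from one sweep, but there is no
  reverse (dimension-decreasing) move.
* Jukes–Cantor only; no rate heterogeneity across sites.
* The mixture split proposal assumes the ordered-means parameterisation;
  label-switching-symmetric priors are handled through that ordering.
* Evidence estimates are unbiased but their variance grows quickly when a
  transformation overlaps the next posterior poorly; the reported per-step
  CESS/ESS diagnostics should be inspected, and particle numbers raised,
  when bridges need many annealing steps.
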