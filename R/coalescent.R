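## Coalescent genealogy inference: state containers, Jukes-Cantor likelihood
## wrappers, the leaf-addition bridge (lineage + height proposals), MCMC
## kernel, sequence orderings, consensus trees, and the online sampler.

DNA_LEVELS <- c("a", "c", "g", "t")

#' DNA alignment container
#'
#' Stores aligned sequences as an integer matrix (rows are sequences, values
#' 1..4 coding a, c, g, t). Sequences must have equal length and contain only
#' unambiguous bases.
#'
#' @param sequences character vector of equal-length DNA strings, or a
#'   character matrix with one row per sequence and one base per column.
#' @param labels sequence names (defaults to names of `sequences` or `seq1`,
#'   `seq2`, ...).
#' @return a list of class `dna_alignment` with fields `codes` (integer
#'   matrix), `labels`, `n_sequences`, `n_sites`.
#' @export
dna_alignment <- function(sequences, labels = NULL) {
  if (is.matrix(sequences)) {
    chars <- tolower(sequences)
  } else {
    sequences <- as.character(sequences)
    if (length(unique(nchar(sequences))) != 1)
      stop("sequences must have equal length")
    chars <- do.call(rbind, strsplit(tolower(sequences), ""))
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(chars))) rownames(chars)
              else if (!is.matrix(sequences) && !is.null(names(sequences))) names(sequences)
              else paste0("seq", seq_len(nrow(chars)))
  }
  codes <- matrix(match(chars, DNA_LEVELS), nrow = nrow(chars))
  if (anyNA(codes)) {
    bad <- which(is.na(codes), arr.ind = TRUE)[1, ]
    stop(sprintf("sequence '%s' has a non-ACGT base at site %d",
                 labels[bad[1]], bad[2]))
  }
  if (anyDuplicated(labels)) stop("duplicate sequence labels")
  structure(list(codes = codes, labels = as.character(labels),
                 n_sequences = nrow(codes), n_sites = ncol(codes)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment: %d sequences x %d sites>\n",
              x$n_sequences, x$n_sites))
  invisible(x)
}

## Subset and/or reorder the rows of an alignment.
subset_alignment <- function(alignment, rows) {
  structure(list(codes = alignment$codes[rows, , drop = FALSE],
                 labels = alignment$labels[rows],
                 n_sequences = length(rows), n_sites = alignment$n_sites),
            class = "dna_alignment")
}

## Compress alignment columns into unique site patterns with counts, using
## the first `rows` sequences. Returns 0-based integer codes for the C++ core.
compress_patterns <- function(alignment, rows = seq_len(alignment$n_sequences)) {
  codes <- alignment$codes[rows, , drop = FALSE]
  key <- apply(codes, 2, paste, collapse = ".")
  first <- !duplicated(key)
  counts <- as.numeric(table(factor(key, levels = key[first])))
  list(patt = codes[, first, drop = FALSE] - 1L, counts = counts)
}

## Pairwise mismatch (SNP) counts between all rows of an alignment.
pairwise_mismatches <- function(alignment) {
  n <- alignment$n_sequences
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- sum(alignment$codes[i, ] != alignment$codes[j, ])
  }
  D
}

#' Coalescent genealogy state
#'
#' A rooted ultrametric genealogy over `n` leaves plus the scaled mutation
#' rate `theta`. Nodes `1..n` are leaves (height 0), nodes `n+1..2n-1` are
#' coalescences; `parent[i]` is the parent index, 0 at the root.
#'
#' @param parent integer parent-pointer vector (0 marks the root).
#' @param heights node heights in coalescent time units (leaves at 0).
#' @param theta scaled mutation rate (> 0).
#' @param n_leaves number of leaves.
#' @return a list of class `coalescent_state`.
#' @export
coalescent_state <- function(parent, heights, theta, n_leaves) {
  parent <- as.integer(parent)
  n_leaves <- as.integer(n_leaves)
  m <- length(parent)
  if (m != 2 * n_leaves - 1) stop("a binary genealogy on n leaves has 2n-1 nodes")
  if (length(heights) != m) stop("heights and parent must have equal length")
  if (sum(parent == 0L) != 1) stop("exactly one root required")
  if (theta <= 0) stop("theta must be positive")
  if (any(heights[seq_len(n_leaves)] != 0)) stop("leaves must have height 0")
  nonroot <- which(parent != 0L)
  if (any(heights[parent[nonroot]] <= heights[nonroot]))
    stop("parent heights must exceed child heights")
  structure(list(parent = parent, heights = as.numeric(heights),
                 theta = theta, n_leaves = n_leaves),
            class = "coalescent_state")
}

## 0-based view of a state for the compiled kernels.
state_for_cpp <- function(state) {
  list(parent = state$parent - 1L, heights = state$heights,
       theta = state$theta, n_leaves = state$n_leaves)
}

#' Kingman coalescent log prior of a genealogy
#'
#' `-sum_a choose(a, 2) * l_a` over inter-coalescence intervals `l_a` during
#' which `a` lineages are extant (the labelled-history density; pair-choice
#' probabilities and exponential rates cancel exactly).
#'
#' @param state a [coalescent_state()].
#' @return the log prior density (`-Inf` for invalid heights).
#' @export
coalescent_log_prior <- function(state) {
  .coal_log_prior_cpp(state$parent - 1L, state$heights, state$n_leaves)
}

#' Jukes-Cantor log-likelihood of an alignment on a genealogy
#'
#' Felsenstein pruning over compressed site patterns. A branch of duration
#' `l` carries `(theta/2) * l` expected substitutions per site; base
#' frequencies are uniform. Row `i` of the alignment sits on leaf `i`.
#'
#' @param state a [coalescent_state()].
#' @param alignment a [dna_alignment()] with `n_leaves` rows.
#' @return the log-likelihood.
#' @export
jc_log_likelihood <- function(state, alignment) {
  if (alignment$n_sequences != state$n_leaves)
    stop("alignment rows must match the number of leaves")
  cp <- compress_patterns(alignment)
  .jc_loglik_cpp(state$parent - 1L, state$heights, state$n_leaves,
                 cp$patt, cp$counts, state$theta)
}

#' Attach a new leaf to a genealogy
#'
#' The new leaf joins the lineage ancestral to leaf `lineage` at time
#' `height`: a new coalescence at `height` is inserted on the edge through
#' which that lineage passes (above the root if `height` exceeds the root
#' height). Leaves keep indices `1..n`; the new leaf becomes `n+1`; old
#' internal nodes shift up by one and the new coalescence is appended last.
#'
#' @param state a [coalescent_state()] with `n` leaves.
#' @param lineage leaf index in `1..n` whose ancestral lineage is joined.
#' @param height attachment time (> 0).
#' @return a [coalescent_state()] with `n + 1` leaves.
#' @export
add_leaf <- function(state, lineage, height) {
  t <- state$n_leaves
  m <- length(state$parent)
  if (lineage < 1 || lineage > t) stop("lineage must index an existing leaf")
  if (height <= 0) stop("attachment height must be positive")
  ## walk up from the chosen leaf to the edge spanning `height`
  v <- lineage
  while (state$parent[v] != 0L && state$heights[state$parent[v]] < height)
    v <- state$parent[v]
  map <- c(seq_len(t), if (m > t) seq.int(t + 2L, m + 1L))
  new_leaf <- t + 1L
  new_int <- m + 2L
  parent <- integer(m + 2L)
  heights <- numeric(m + 2L)
  parent[map] <- ifelse(state$parent == 0L, 0L, map[pmax(state$parent, 1L)])
  heights[map] <- state$heights
  parent[map[v]] <- new_int
  parent[new_leaf] <- new_int
  parent[new_int] <- if (state$parent[v] == 0L) 0L else map[state$parent[v]]
  heights[new_int] <- height
  coalescent_state(parent, heights, state$theta, t + 1L)
}

#' Remove a leaf from a genealogy
#'
#' Deletes leaf `leaf` and its parent coalescence, joining the sibling to the
#' grandparent. Remaining leaves with larger indices shift down by one (the
#' bridge always removes the most recently added leaf, `n`, so old leaves
#' keep their indices there).
#'
#' @param state a [coalescent_state()] with `n >= 2` leaves.
#' @param leaf leaf index to remove (default: the last leaf).
#' @return a [coalescent_state()] with `n - 1` leaves.
#' @export
remove_leaf <- function(state, leaf = state$n_leaves) {
  if (state$n_leaves < 2) stop("cannot remove a leaf from a one-leaf genealogy")
  rt <- .remove_leaf_cpp(state$parent - 1L, state$heights, leaf - 1L)
  coalescent_state(rt$parent + 1L, rt$heights, state$theta, state$n_leaves - 1L)
}

#' Inverse-image lineages of the most recent leaf addition
#'
#' The set of leaves `s` for which attaching the new leaf to the lineage of
#' `s` at its current attachment height reproduces the genealogy: the leaves
#' of the sibling subtree of `new_leaf` (all old leaves when the new leaf
#' attaches above the old root). This is the set the proposal density is
#' marginalised over.
#'
#' @param state a [coalescent_state()].
#' @param new_leaf index of the most recently added leaf.
#' @return an integer vector of leaf indices.
#' @export
inverse_image_lineages <- function(state, new_leaf = state$n_leaves) {
  sort(.lambda_set_cpp(state$parent - 1L, state$n_leaves, new_leaf - 1L))
}

## ---------------------------------------------------------------------------
## proposals

#' Lineage-choice proposal weights
#'
#' The probability of guiding the new sequence toward existing leaf `s` is
#' proportional to `r^(power * M_s)`, where `r` is
#' `N theta / (t + N theta)`,
#' where `M_s` counts mismatching sites between the new sequence and leaf
#' `s`, `N` is the number of sites and `t` the current number of leaves.
#' Mismatch-free leaves get the largest weight.
#'
#' @param mismatches integer vector `M_s` over the `t` existing leaves.
#' @param n_sites alignment length `N`.
#' @param theta scaled mutation rate the proposal is tuned at.
#' @param power annealing exponent on the mismatch counts (1 = full guiding,
#'   0 = uniform).
#' @return normalised probabilities over the `t` leaves.
#' @export
lineage_weights <- function(mismatches, n_sites, theta, power = 1) {
  t <- length(mismatches)
  log_r <- log(n_sites * theta) - log(t + n_sites * theta)
  lw <- power * mismatches * log_r
  exp(lw - logsumexp(lw))
}

#' Attachment-height proposal for one candidate lineage
#'
#' Either a log-normal density fitted by a Laplace approximation (in log
#' height) to the pairwise Jukes-Cantor likelihood of the new sequence
#' against leaf `s`, or the `Exp(1)` density. The Laplace fit falls back to
#' `Exp(1)` when the two sequences are identical (no interior mode) or the
#' curvature at the mode is not usable.
#'
#' @param mismatch number of mismatching sites against leaf `s`.
#' @param n_sites alignment length.
#' @param theta scaled mutation rate the proposal is tuned at.
#' @param kind `"laplace"` or `"exp1"`.
#' @return a list with `kind` (`"lognormal"` or `"exp1"`), `meanlog`,
#'   `sdlog`, and closures `sample(n)` and `log_density(h)`.
#' @export
height_proposal <- function(mismatch, n_sites, theta, kind = c("laplace", "exp1")) {
  kind <- match.arg(kind)
  make <- function(type, meanlog = NA_real_, sdlog = NA_real_) {
    if (type == "exp1") {
      list(kind = "exp1", meanlog = NA_real_, sdlog = NA_real_,
           sample = function(n) rexp(n, 1),
           log_density = function(h) ifelse(h > 0, -h, -Inf))
    } else {
      list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog,
           sample = function(n) exp(rnorm(n, meanlog, sdlog)),
           log_density = function(h) dlnorm(h, meanlog, sdlog, log = TRUE))
    }
  }
  if (kind == "exp1" || mismatch == 0) return(make("exp1"))
  ## pairwise JC log-likelihood of divergence time h (total path theta * h),
  ## in log-height coordinates, with the log-height Jacobian
  g <- function(x) {
    e <- exp(-4 * theta * exp(x) / 3)
    mismatch * log(0.25 - 0.25 * e) + (n_sites - mismatch) * log(0.25 + 0.75 * e) + x
  }
  opt <- optimize(g, lower = log(1e-10), upper = log(1e4), maximum = TRUE)
  x0 <- opt$maximum
  eps <- 1e-4
  curv <- (g(x0 + eps) - 2 * g(x0) + g(x0 - eps)) / eps^2
  if (!is.finite(curv) || curv >= -1e-8 || x0 < log(1e-9) || x0 > log(5e3))
    return(make("exp1"))
  make("lognormal", meanlog = x0, sdlog = 1 / sqrt(-curv))
}

## ---------------------------------------------------------------------------
## the leaf-addition bridge

#' Bridge from the t-leaf to the (t+1)-leaf coalescent posterior
#'
#' The transformation attaches sequence `t+1` to each particle's genealogy:
#' a guiding leaf is drawn from [lineage_weights()] and an attachment height
#' from the per-leaf [height_proposal()]. The insertion is measure-preserving
#' (no Jacobian); the start density marginalises the proposal over the
#' inverse-image lineages. Proposal parameters are tuned once per bridge at
#' `theta_hat` (a population summary) so the start density stays closed-form
#' inside the MCMC moves.
#'
#' @param alignment the full [dna_alignment()], already in addition order.
#' @param t number of leaves before the addition (sequence `t+1` is added).
#' @param theta_hat mutation rate at which the proposals are tuned
#'   (typically the weighted population mean).
#' @param lineage_power exponent passed to [lineage_weights()].
#' @param height_kind `"laplace"` or `"exp1"`, passed to [height_proposal()].
#' @param theta_shape,theta_rate Gamma prior on `theta`.
#' @return a bridge usable with [run_bridge()]; also carries `bridge_data`
#'   for the compiled kernels.
#' @export
leaf_addition_bridge <- function(alignment, t, theta_hat, lineage_power = 1,
                                 height_kind = c("laplace", "exp1"),
                                 theta_shape = 1, theta_rate = 5) {
  height_kind <- match.arg(height_kind)
  stopifnot(t >= 1, alignment$n_sequences >= t + 1)
  new_codes <- alignment$codes[t + 1L, ]
  mism <- vapply(seq_len(t), function(s) sum(alignment$codes[s, ] != new_codes),
                 integer(1))
  chi_g <- lineage_weights(mism, alignment$n_sites, theta_hat, lineage_power)
  props <- lapply(seq_len(t), function(s)
    height_proposal(mism[s], alignment$n_sites, theta_hat, height_kind))
  use_lap <- vapply(props, function(p) p$kind == "lognormal", logical(1))
  bridge_data <- list(
    full_patt = compress_patterns(alignment, seq_len(t + 1L))$patt,
    full_counts = compress_patterns(alignment, seq_len(t + 1L))$counts,
    red_patt = compress_patterns(alignment, seq_len(t))$patt,
    red_counts = compress_patterns(alignment, seq_len(t))$counts,
    theta_shape = theta_shape, theta_rate = theta_rate,
    log_chi_g = log(chi_g),
    lap_mean = vapply(props, function(p) if (is.na(p$meanlog)) 0 else p$meanlog, numeric(1)),
    lap_sd = vapply(props, function(p) if (is.na(p$sdlog)) 1 else p$sdlog, numeric(1)),
    use_lap = use_lap)
  transform <- function(values) {
    lapply(values, function(state) {
      s <- sample.int(t, 1L, prob = chi_g)
      h <- props[[s]]$sample(1)
      add_leaf(state, s, h)
    })
  }
  structure(list(
    transform = transform,
    log_phi_from = function(values)
      .coal_log_phi_cpp(lapply(values, state_for_cpp), bridge_data, FALSE),
    log_phi_to = function(values)
      .coal_log_phi_cpp(lapply(values, state_for_cpp), bridge_data, TRUE),
    bridge_data = bridge_data,
    chi_g = chi_g, height_proposals = props, t = t
  ), class = "tsmc_bridge")
}

#' Metropolis-within-Gibbs kernel for coalescent bridges
#'
#' One sweep per particle: a height slide for every non-root coalescence, a
#' multiplicative root-height move, `n_topo` height-preserving
#' subtree-prune-regraft moves (detach a subtree and regraft at the same
#' height onto a uniformly chosen edge spanning it -- a symmetric proposal),
#' and a log-scale random walk on `theta`. All moves are accepted against
#' the gamma-bridged density. Proposal scales adapt to the weighted
#' population spread.
#'
#' @param topology_moves enable the subtree-prune-regraft moves?
#' @param n_topo regraft attempts per sweep.
#' @return a kernel `function(values, gamma, bridge, weights)` for
#'   [run_bridge()].
#' @export
coalescent_mcmc_kernel <- function(topology_moves = TRUE, n_topo = 2L) {
  function(values, gamma, bridge, weights) {
    thetas <- vapply(values, function(s) s$theta, numeric(1))
    roots <- vapply(values, function(s) max(s$heights), numeric(1))
    wsd <- function(x) {
      mu <- sum(weights * x)
      sqrt(max(sum(weights * (x - mu)^2), 0))
    }
    sc_theta <- max(2.38 * wsd(log(thetas)), 0.05)
    sc_root <- max(2.38 * wsd(log(roots)), 0.05)
    nleaf <- values[[1]]$n_leaves
    sc_height <- max(sum(weights * roots) / (2 * nleaf), 1e-8)
    n_acc <- 0L; n_prop <- 0L
    out <- lapply(values, function(state) {
      sw <- .coal_mcmc_sweep_cpp(state$parent - 1L, state$heights, state$theta,
                                 state$n_leaves, gamma, bridge$bridge_data,
                                 sc_height, sc_root, sc_theta,
                                 topology_moves, as.integer(n_topo), 1L)
      n_acc <<- n_acc + sw$n_accept
      n_prop <<- n_prop + sw$n_prop
      coalescent_state(sw$parent + 1L, sw$heights, sw$theta, state$n_leaves)
    })
    list(values = out, accept = if (n_prop > 0) n_acc / n_prop else NA_real_)
  }
}

## ---------------------------------------------------------------------------
## sequence orderings and consensus

#' Greedy sequence addition orderings
#'
#' `"given"` keeps the input order. `"nearest"` starts from the pair with the
#' fewest mismatching sites and repeatedly appends the sequence with the
#' smallest mismatch count to any already-selected sequence; `"furthest"`
#' starts from the most-mismatching pair and appends the sequence with the
#' largest mismatch count to any selected sequence. Ties resolve to the
#' earliest input index.
#'
#' @param alignment a [dna_alignment()].
#' @param mode `"given"`, `"nearest"` or `"furthest"`.
#' @return a permutation of `1..n` (addition order).
#' @export
sequence_ordering <- function(alignment, mode = c("given", "nearest", "furthest")) {
  mode <- match.arg(mode)
  n <- alignment$n_sequences
  if (mode == "given" || n <= 2) return(seq_len(n))
  D <- pairwise_mismatches(alignment)
  pick <- if (mode == "nearest") which.min else which.max
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  best <- pick(D[pairs])
  sel <- as.integer(pairs[best, ])
  rest <- setdiff(seq_len(n), sel)
  while (length(rest) > 0) {
    crit <- vapply(rest, function(i) {
      d <- D[i, sel]
      if (mode == "nearest") min(d) else max(d)
    }, numeric(1))
    k <- rest[pick(crit)]
    sel <- c(sel, k)
    rest <- setdiff(rest, k)
  }
  sel
}

#' Weighted majority-rule consensus tree
#'
#' Counts the (weighted) support of every clade across the sampled
#' genealogies and keeps clades whose support exceeds 1/2; majority clades
#' are automatically compatible, so they assemble into a single, possibly
#' multifurcating rooted tree. Node labels carry the supports.
#'
#' @param states list of [coalescent_state()] objects over the same leaves.
#' @param weights particle weights (default uniform), normalised internally.
#' @param labels tip labels (default `t1..tn`).
#' @return an `ape::phylo` tree; `node.label` holds clade supports, and
#'   attribute `"supports"` maps clade keys (sorted leaf indices joined by
#'   `","`) to supports.
#' @export
majority_consensus <- function(states, weights = NULL, labels = NULL) {
  n <- states[[1]]$n_leaves
  if (is.null(weights)) weights <- rep(1, length(states))
  weights <- weights / sum(weights)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  support <- new.env(parent = emptyenv())
  clade_leaves <- function(state) {
    m <- length(state$parent)
    sets <- vector("list", m)
    for (i in seq_len(n)) sets[[i]] <- i
    ord <- order(state$heights[(n + 1):m]) + n
    kids <- split(seq_len(m)[state$parent != 0], state$parent[state$parent != 0])
    for (v in ord) sets[[v]] <- sort(c(sets[[kids[[as.character(v)]][1]]],
                                       sets[[kids[[as.character(v)]][2]]]))
    sets[(n + 1):m]
  }
  for (k in seq_along(states)) {
    for (cl in clade_leaves(states[[k]])) {
      key <- paste(cl, collapse = ",")
      support[[key]] <- (if (is.null(support[[key]])) 0 else support[[key]]) + weights[k]
    }
  }
  keys <- ls(support)
  supp <- vapply(keys, function(k) support[[k]], numeric(1))
  keep <- keys[supp > 0.5]
  root_key <- paste(seq_len(n), collapse = ",")
  if (!(root_key %in% keep)) {
    keep <- c(keep, root_key)
    supp[root_key] <- 1
  }
  clades <- lapply(keep, function(k) as.integer(strsplit(k, ",")[[1]]))
  sizes <- lengths(clades)
  ord <- order(-sizes)
  clades <- clades[ord]
  keep <- keep[ord]
  n_int <- length(clades)
  ## parent of each clade/tip = smallest kept clade strictly containing it
  node_of <- function(i) n + i  # internal ape ids in decreasing-size order
  parent_clade <- function(leafset, self) {
    cand <- which(vapply(seq_len(n_int), function(j)
      j != self && length(clades[[j]]) > length(leafset) &&
        all(leafset %in% clades[[j]]), logical(1)))
    if (length(cand) == 0) return(NA_integer_)
    cand[which.min(lengths(clades)[cand])]
  }
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    p <- parent_clade(i, self = 0L)
    edges <- rbind(edges, c(node_of(p), i))
  }
  for (j in seq_len(n_int)) {
    p <- parent_clade(clades[[j]], self = j)
    if (!is.na(p)) edges <- rbind(edges, c(node_of(p), node_of(j)))
  }
  tree <- structure(list(edge = edges, tip.label = labels, Nnode = n_int,
                         node.label = sprintf("%.3f", unname(supp[keep]))),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "supports") <- stats::setNames(unname(supp[keep]), keep)
  tree
}

## ---------------------------------------------------------------------------
## ape interop

#' Convert a coalescent state to an `ape::phylo` tree
#'
#' @param state a [coalescent_state()] with at least two leaves.
#' @param labels tip labels (default `t1..tn`).
#' @return an `ape::phylo` object with branch lengths in coalescent units.
#' @export
state_to_phylo <- function(state, labels = NULL) {
  n <- state$n_leaves
  if (n < 2) stop("ape trees need at least two tips")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  m <- length(state$parent)
  kids <- split(seq_len(m)[state$parent != 0], state$parent[state$parent != 0])
  root <- which(state$parent == 0L)
  ## renumber internals in preorder so the root is n+1 and edges are cladewise
  newid <- integer(m)
  newid[seq_len(n)] <- seq_len(n)
  edges <- matrix(0L, 0, 2); lens <- numeric(0); nxt <- n + 1L
  walk2 <- function(v) {
    newid[v] <<- nxt
    nxt <<- nxt + 1L
    for (c in kids[[as.character(v)]]) {
      edges <<- rbind(edges, c(newid[v], if (c <= n) c else NA))
      lens <<- c(lens, state$heights[v] - state$heights[c])
      if (c > n) {
        edges[nrow(edges), 2] <<- nxt
        walk2(c)
      }
    }
  }
  walk2(root)
  structure(list(edge = edges, edge.length = lens, tip.label = labels,
                 Nnode = n - 1L),
            class = "phylo", order = "cladewise")
}

#' Convert an ultrametric `ape::phylo` tree to a coalescent state
#'
#' @param phy a rooted, binary, ultrametric `ape::phylo` tree.
#' @param theta scaled mutation rate to attach.
#' @param tol tolerance for the ultrametricity check, relative to tree height.
#' @return a [coalescent_state()]; tip `i` of `phy` becomes leaf `i`.
#' @export
phylo_to_state <- function(phy, theta, tol = 1e-6) {
  n <- length(phy$tip.label)
  if (!ape::is.rooted(phy) || !ape::is.binary(phy)) stop("need a rooted binary tree")
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth) - depth
  if (any(abs(height[seq_len(n)]) > tol * max(depth)))
    stop("tree is not ultrametric")
  height[seq_len(n)] <- 0
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  coalescent_state(parent, height, theta, n)
}

## ---------------------------------------------------------------------------
## the online sampler

#' Online coalescent inference by transformation SMC
#'
#' Starts from the exact single-sequence posterior (`theta` from its Gamma
#' prior; evidence `(1/4)^N`) and adds one sequence at a time through
#' [leaf_addition_bridge()]s, annealing each with CESS-adaptive geometric
#' steps, stratified resampling and Metropolis-within-Gibbs rejuvenation.
#' Evidence estimates accumulate across additions, so the returned
#' `log_evidence_path[t]` estimates the marginal likelihood of the first `t`
#' sequences.
#'
#' @param alignment a [dna_alignment()].
#' @param n_particles number of particles.
#' @param config an [anneal_config()]; the default uses `beta = 0.95`,
#'   `alpha = 0.5` and 2 MCMC sweeps per intermediate distribution.
#' @param ordering sequence addition order: `"nearest"`, `"furthest"`,
#'   `"given"`, or an explicit permutation of `1..n`.
#' @param lineage_power exponent of the guided lineage proposal.
#' @param height_kind `"laplace"` or `"exp1"` attachment-height proposals.
#' @param topology_moves enable subtree-prune-regraft rejuvenation?
#' @param theta_shape,theta_rate Gamma prior on `theta` (shape/rate).
#' @return a list of class `tsmc_coalescent_fit` with the final particle
#'   `system`, `log_evidence` (final), `log_evidence_path` (per number of
#'   sequences), posterior `theta` draws and weights, the addition `order`
#'   and per-bridge `reports`.
#' @export
tsmc_coalescent <- function(alignment, n_particles = 250,
                            config = anneal_config(cess_fraction = 0.95,
                                                   resample_fraction = 0.5),
                            ordering = "nearest", lineage_power = 1,
                            height_kind = c("laplace", "exp1"),
                            topology_moves = TRUE,
                            theta_shape = 1, theta_rate = 5,
                            keep_history = FALSE) {
  height_kind <- match.arg(height_kind)
  n <- alignment$n_sequences
  if (n < 2) stop("need at least two sequences")
  ord <- if (is.character(ordering)) sequence_ordering(alignment, ordering)
         else as.integer(ordering)
  if (!identical(sort(ord), seq_len(n))) stop("ordering must be a permutation")
  aln <- subset_alignment(alignment, ord)
  P <- n_particles
  log_z1 <- alignment$n_sites * log(0.25)
  values <- lapply(rgamma(P, theta_shape, rate = theta_rate), function(th)
    coalescent_state(0L, 0, th, 1L))
  system <- particle_system(values, P, log_z0 = log_z1)
  kernel <- coalescent_mcmc_kernel(topology_moves = topology_moves)
  reports <- list()
  history <- if (keep_history) vector("list", n - 1)
  path <- numeric(n)
  path[1] <- log_z1
  for (t in seq_len(n - 1)) {
    w <- normalise_log_weights(system$log_weights)
    theta_hat <- sum(w * vapply(system$values, function(s) s$theta, numeric(1)))
    bridge <- leaf_addition_bridge(aln, t, theta_hat,
                                   lineage_power = lineage_power,
                                   height_kind = height_kind,
                                   theta_shape = theta_shape,
                                   theta_rate = theta_rate)
    bridge$select <- function(values, idx) values[idx]
    system <- run_bridge(system, bridge, kernel, config)
    reports[[t]] <- attr(system, "report")
    path[t + 1] <- log_evidence(system)
    if (keep_history)
      history[[t]] <- list(values = system$values,
                           weights = normalise_log_weights(system$log_weights))
  }
  w <- normalise_log_weights(system$log_weights)
  structure(list(system = system,
                 log_evidence = log_evidence(system),
                 log_evidence_path = path,
                 theta = vapply(system$values, function(s) s$theta, numeric(1)),
                 weights = w,
                 order = ord, labels = aln$labels,
                 reports = do.call(rbind, reports),
                 history = if (keep_history) history),
            class = "tsmc_coalescent_fit")
}

#' @export
print.tsmc_coalescent_fit <- function(x, ...) {
  cat(sprintf("<tsmc_coalescent_fit: %d sequences, log evidence %.3f, E[theta] %.4f>\n",
              length(x$order), x$log_evidence, sum(x$weights * x$theta)))
  invisible(x)
}
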