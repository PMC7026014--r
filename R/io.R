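## Readers, writers and run orchestration: FASTA/Newick/CSV/JSON interchange
## and the reproducible `run_mixture()` / `run_coalescent()` entry points the
## command-line interface wraps.

input_error <- function(msg) {
  stop(errorCondition(msg, class = c("tsmc_input_error", "error", "condition")))
}

#' Read a FASTA alignment
#'
#' Strict parse: all sequences must have equal length, contain only
#' unambiguous bases (`N`-masked sites can optionally be dropped), and carry
#' unique labels. Errors name the offending records.
#'
#' @param path FASTA file.
#' @param mask_n drop alignment columns containing `N`/`n` instead of
#'   rejecting them?
#' @return a [dna_alignment()].
#' @export
read_fasta <- function(path, mask_n = FALSE) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  seqs <- tryCatch(ape::read.FASTA(path),
                   error = function(e) input_error(
                     sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(seqs) == 0) input_error(sprintf("no records in '%s'", path))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    input_error(sprintf(
      "unequal sequence lengths: record '%s' has %d sites but record '%s' has %d",
      names(seqs)[1], lens[1], names(seqs)[bad], lens[bad]))
  }
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    input_error(sprintf("duplicate record label '%s'", dup))
  }
  chars <- tolower(do.call(rbind, as.character(seqs)))
  if (mask_n) {
    keep <- colSums(chars == "n") == 0
    if (!any(keep)) input_error("all alignment columns are N-masked")
    chars <- chars[, keep, drop = FALSE]
  }
  bad <- which(!(chars %in% DNA_LEVELS))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(chars))
    input_error(sprintf("record '%s' has a non-ACGT base ('%s') at site %d",
                        names(seqs)[rc[1]], chars[bad[1]], rc[2]))
  }
  dna_alignment(chars, labels = names(seqs))
}

#' Write a FASTA alignment
#'
#' @param alignment a [dna_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  seq_strings <- apply(matrix(DNA_LEVELS[alignment$codes],
                              nrow = alignment$n_sequences), 1, paste,
                       collapse = "")
  writeLines(as.vector(rbind(paste0(">", alignment$labels), seq_strings)), path)
  invisible(path)
}

#' Write a genealogy (or any tree) as Newick
#'
#' Coalescent states are converted with [state_to_phylo()] (branch lengths in
#' coalescent units); `ape::phylo` objects -- including consensus trees whose
#' `node.label` carries clade supports -- are written as-is.
#'
#' @param tree a [coalescent_state()] or `ape::phylo` object.
#' @param path output file.
#' @param labels tip labels when converting a state.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, labels = NULL) {
  phy <- if (inherits(tree, "coalescent_state")) state_to_phylo(tree, labels)
         else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path Newick file (one tree).
#' @param theta if non-`NULL`, convert the (ultrametric) tree to a
#'   [coalescent_state()] with this mutation rate.
#' @return an `ape::phylo` object, or a [coalescent_state()] when `theta` is
#'   given.
#' @export
read_newick <- function(path, theta = NULL) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) input_error(
                    sprintf("malformed Newick '%s': %s", path, conditionMessage(e))))
  if (is.null(phy)) input_error(sprintf("malformed Newick '%s'", path))
  if (is.null(theta)) phy else phylo_to_state(phy, theta)
}

#' Read univariate observations from a CSV file
#'
#' Accepts a single-column file (with or without header) or any file with a
#' `y` column.
#'
#' @param path CSV file.
#' @return a numeric vector.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  first_line <- readLines(path, n = 1)
  first_field <- strsplit(first_line, ",")[[1]][1]
  has_header <- is.na(suppressWarnings(as.numeric(first_field)))
  df <- tryCatch(utils::read.csv(path, header = has_header),
                 error = function(e) input_error(
                   sprintf("malformed CSV '%s': %s", path, conditionMessage(e))))
  col <- if ("y" %in% names(df)) df$y
         else if (ncol(df) == 1) df[[1]]
         else input_error(sprintf("'%s' needs a 'y' column", path))
  y <- suppressWarnings(as.numeric(col))
  if (anyNA(y)) input_error(sprintf("non-numeric observations in '%s'", path))
  y
}

## Weighted quantiles of a particle sample (inverse weighted ECDF).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

write_run_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a reproducible mixture model-comparison analysis
#'
#' Estimates the log marginal likelihood of every Gaussian mixture model
#' `t = 1..max_components` by transformation SMC and/or per-model
#' prior-to-posterior annealing (SMC2), then writes a JSON report (config
#' echo, seed, per-model log-evidence, Gaussian density-evaluation counts)
#' and a per-step diagnostics CSV (gamma schedule, ESS, CESS, resampling,
#' acceptance rates) to `out_dir`.
#'
#' @param data observations: a numeric vector, a [mixture_dataset()], or a
#'   path to a CSV file.
#' @param out_dir output directory (created if missing).
#' @param particles,cess_fraction,resample_fraction SMC settings.
#' @param max_components largest model `T`.
#' @param move,weight_mode transformation SMC variant, see
#'   [bridge_for_transition()].
#' @param method `"tsmc"`, `"smc2"`, or `"both"`.
#' @param seed RNG seed (echoed into the report).
#' @return invisibly, the parsed report list.
#' @export
run_mixture <- function(data, out_dir, particles = 500, cess_fraction = 0.99,
                        resample_fraction = 0.5, max_components = 8,
                        move = "split", weight_mode = "marginal",
                        method = c("tsmc", "smc2", "both"), seed = 1) {
  method <- match.arg(method)
  if (is.character(data)) data <- read_observations_csv(data)
  if (!inherits(data, "mixture_dataset")) data <- mixture_dataset(data)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- anneal_config(cess_fraction = cess_fraction,
                          resample_fraction = resample_fraction)
  report <- list(subcommand = "mixture", seed = seed,
                 config = list(particles = particles,
                               cess_fraction = cess_fraction,
                               resample_fraction = resample_fraction,
                               max_components = max_components,
                               move = move, weight_mode = weight_mode,
                               method = method,
                               n_observations = data$n))
  diag_rows <- list()
  if (method %in% c("tsmc", "both")) {
    set.seed(seed)
    fit <- tsmc_mixture(data, max_components, move = move, mode = weight_mode,
                        n_particles = particles, config = config)
    report$tsmc <- list(log_evidence = unname(fit$log_evidence),
                        models = seq_len(max_components),
                        best_model = unname(which.max(fit$log_evidence)),
                        n_gauss_evals = fit$n_gauss_evals)
    for (r in fit$reports)
      diag_rows[[length(diag_rows) + 1L]] <- cbind(method = "tsmc", r)
  }
  if (method %in% c("smc2", "both")) {
    priors <- mixture_priors(data, max_components)
    logz <- numeric(max_components)
    for (t in seq_len(max_components)) {
      set.seed(seed + t)
      reset_eval_counter()
      sys <- smc2_evidence(t, data, priors, particles, config,
                           return_system = TRUE)
      logz[t] <- log_evidence(sys)
      diag_rows[[length(diag_rows) + 1L]] <-
        cbind(method = "smc2", attr(sys, "report"))
    }
    report$smc2 <- list(log_evidence = logz,
                        models = seq_len(max_components),
                        best_model = unname(which.max(logz)),
                        n_gauss_evals = get_eval_counter())
  }
  write_run_json(report, file.path(out_dir, "mixture_evidence.json"))
  utils::write.csv(do.call(rbind, diag_rows),
                   file.path(out_dir, "mixture_diagnostics.csv"),
                   row.names = FALSE)
  invisible(report)
}

#' Run a reproducible online coalescent analysis
#'
#' Orders the sequences, runs leaf-addition transformation SMC over
#' `t = 1..n`, and writes to `out_dir`: a JSON report (config echo, seed,
#' per-step log evidence, `theta` posterior summaries, the number of
#' intermediate distributions used), a diagnostics CSV, per-step majority
#' consensus trees (`consensus.nwk`, one Newick line per addition step, clade
#' supports as node labels) and a weighted resample of posterior genealogies
#' (`posterior_trees.nwk`).
#'
#' @param alignment a [dna_alignment()] or path to a FASTA file.
#' @param out_dir output directory (created if missing).
#' @param particles,cess_fraction,resample_fraction SMC settings.
#' @param ordering,lineage_power,height_proposal,topology_moves sampler
#'   options, see [tsmc_coalescent()].
#' @param n_tree_samples number of genealogies resampled into
#'   `posterior_trees.nwk`.
#' @param seed RNG seed (echoed into the report).
#' @return invisibly, the parsed report list.
#' @export
run_coalescent <- function(alignment, out_dir, particles = 250,
                           cess_fraction = 0.95, resample_fraction = 0.5,
                           ordering = "nearest", lineage_power = 1,
                           height_proposal = "laplace", topology_moves = TRUE,
                           n_tree_samples = 100, seed = 1) {
  if (is.character(alignment)) alignment <- read_fasta(alignment)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- anneal_config(cess_fraction = cess_fraction,
                          resample_fraction = resample_fraction)
  set.seed(seed)
  fit <- tsmc_coalescent(alignment, n_particles = particles, config = config,
                         ordering = ordering, lineage_power = lineage_power,
                         height_kind = height_proposal,
                         topology_moves = topology_moves, keep_history = TRUE)
  qs <- weighted_quantile(fit$theta, fit$weights, c(0.05, 0.5, 0.95))
  report <- list(
    subcommand = "coalescent", seed = seed,
    config = list(particles = particles, cess_fraction = cess_fraction,
                  resample_fraction = resample_fraction, ordering = ordering,
                  lineage_power = lineage_power,
                  height_proposal = height_proposal,
                  topology_moves = topology_moves,
                  n_sequences = alignment$n_sequences,
                  n_sites = alignment$n_sites),
    addition_order = fit$order,
    ordered_labels = fit$labels,
    log_evidence_path = fit$log_evidence_path,
    log_evidence = fit$log_evidence,
    theta = list(mean = sum(fit$weights * fit$theta),
                 q05 = qs[1], median = qs[2], q95 = qs[3]),
    n_intermediate_distributions = nrow(fit$reports))
  write_run_json(report, file.path(out_dir, "coalescent_evidence.json"))
  utils::write.csv(fit$reports, file.path(out_dir, "coalescent_diagnostics.csv"),
                   row.names = FALSE)
  ## per-step consensus trees, one Newick line per addition step
  cons_lines <- vapply(seq_along(fit$history), function(t) {
    h <- fit$history[[t]]
    cons <- majority_consensus(h$values, h$weights,
                               labels = fit$labels[seq_len(t + 1L)])
    ape::write.tree(cons)
  }, character(1))
  writeLines(cons_lines, file.path(out_dir, "consensus.nwk"))
  ## weighted resample of posterior genealogies
  set.seed(seed + 1)
  idx <- sample.int(length(fit$weights), n_tree_samples, replace = TRUE,
                    prob = fit$weights)
  tree_lines <- vapply(idx, function(i)
    ape::write.tree(state_to_phylo(fit$system$values[[i]], labels = fit$labels)),
    character(1))
  writeLines(tree_lines, file.path(out_dir, "posterior_trees.nwk"))
  invisible(report)
}
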