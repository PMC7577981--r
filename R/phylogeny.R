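#' Error model for mutation-tree inference
#'
#' @param fpr Global false-positive rate (probability of observing a mutant
#'   call in a truly wild-type cell); default 0.01.
#' @param fnr False-negative rate (allele dropout): scalar or per-locus.
#' @param learn_fnr Learn the FNR during MCMC instead of fixing it.
#' @param locus_specific Learn an independent FNR per locus with a Gaussian
#'   prior centred on the sample estimate.
#' @param prior_mean Prior mean for locus-specific FNRs (default: `fnr`).
#' @param prior_sd Prior standard deviation for locus-specific FNRs
#'   (default 0.002).
#' @return An `error_model` list.
#' @export
error_model <- function(fpr = 0.01, fnr = 0.058, learn_fnr = FALSE,
                        locus_specific = FALSE, prior_mean = NULL,
                        prior_sd = 0.002) {
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  if (any(fnr <= 0 | fnr >= 1)) stop("fnr must be in (0, 1)")
  if (prior_sd <= 0) stop("prior_sd must be positive")
  structure(list(fpr = fpr, fnr = fnr, learn_fnr = learn_fnr,
                 locus_specific = locus_specific,
                 prior_mean = prior_mean %||% mean(fnr),
                 prior_sd = prior_sd),
            class = "error_model")
}

#' MCMC configuration
#'
#' @param chain_length Iterations per chain.
#' @param burn_in Burn-in fraction of the chain.
#' @param thinning Keep every `thinning`-th post-burn-in state.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed.
#' @param move_weights Relative weights of the tree moves
#'   (prune-and-reattach, node-label swap, subtree swap).
#' @param beta_move_prob Probability of proposing an error-rate update at an
#'   iteration when the FNR is being learned.
#' @param prop_sd Random-walk proposal SD for the global FNR.
#' @param prop_sd_locus Proposal SD for locus-specific FNRs.
#' @param model_id Optional model configuration 1-4 (see [mcmc_infer()]).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chain_length = 20000, burn_in = 0.25, thinning = 10,
                        n_chains = 3, seed = 1L,
                        move_weights = c(prune = 0.5, label_swap = 0.25,
                                         subtree_swap = 0.25),
                        beta_move_prob = 0.2, prop_sd = 0.1,
                        prop_sd_locus = 0.005, model_id = NULL) {
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be a fraction in [0, 1)")
  if (chain_length <= 1 / (1 - burn_in)) stop("chain too short for burn-in")
  if (!is.null(model_id) && !model_id %in% 1:4)
    stop("model_id must be one of 1, 2, 3, 4")
  if (length(move_weights) != 3 || any(move_weights < 0))
    stop("move_weights must be three non-negative weights")
  structure(list(chain_length = as.integer(chain_length), burn_in = burn_in,
                 thinning = as.integer(thinning),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 move_weights = move_weights / sum(move_weights),
                 beta_move_prob = beta_move_prob, prop_sd = prop_sd,
                 prop_sd_locus = prop_sd_locus, model_id = model_id),
            class = "mcmc_config")
}

# collapse identical genotype rows (per timepoint) to weighted patterns
collapse_patterns <- function(genotypes, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- rep(1L, nrow(genotypes))
  tp <- as.integer(factor(timepoints))
  key <- paste(tp, apply(genotypes, 1L, paste, collapse = ","))
  idx <- match(key, unique(key))
  first <- which(!duplicated(idx))
  list(D = genotypes[first, , drop = FALSE],
       w = as.numeric(tabulate(idx, nbins = length(first))),
       tp = tp[first],
       cell_pattern = idx,
       tp_levels = levels(factor(timepoints)))
}

check_binary_view <- function(genotypes) {
  if (!all(genotypes %in% c(0L, 1L, 3L)))
    stop("binary view required: codes must be in {0, 1, 3}; ",
         "use encode_zygosity() for matrices with homozygous calls")
}

#' Marginal log-likelihood of a genotype matrix given a mutation tree
#'
#' The observation model: a truly mutant entry is observed wild type with
#' probability `fnr[j]` (allele dropout), a truly wild-type entry is
#' observed mutant with probability `fpr`, and missing entries (code 3)
#' contribute no likelihood factor. Each cell's attachment to a tree node is
#' marginalized under a uniform prior over the `n_events + 1` nodes:
#' \deqn{\log L = \sum_c \log \frac{1}{E+1} \sum_v \prod_j P(D_{cj} \mid E_j(v))}
#' where \eqn{E_j(v) = 1} iff event \eqn{j} is an ancestor-or-self of
#' \eqn{v}.
#'
#' @param genotypes Integer code matrix (cells x loci), codes in
#'   `{0, 1, 3}`.
#' @param tree A [mutation_tree()] whose events correspond to the loci
#'   (columns), in order.
#' @param errors An [error_model()].
#' @return Log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(genotypes, tree, errors) {
  check_binary_view(genotypes)
  if (length(tree$parent) != ncol(genotypes))
    stop("tree events must cover all loci")
  fnr <- rep_len(errors$fnr, ncol(genotypes))
  cp <- collapse_patterns(genotypes)
  cpp_tree_loglik(cp$D, cp$w, errors$fpr, fnr, tree$parent)
}

#' Infer a mutation tree by MCMC
#'
#' Metropolis-Hastings over mutation trees (prune-and-reattach, node-label
#' swap, subtree swap) and, when the FNR is learned, over the error rate
#' (Gaussian random walk reflected at the unit interval; uniform prior for
#' the global rate, Gaussian prior centred on the sample estimate for
#' locus-specific rates). The four standard model configurations:
#' \describe{
#'   \item{1}{all cells (missing genotypes allowed), FNR learned}
#'   \item{2}{all cells, FNR fixed to the platform/sample estimate}
#'   \item{3}{only cells with complete genotypes, FNR learned}
#'   \item{4}{only cells with complete genotypes, FNR fixed}
#' }
#'
#' @param genotypes Integer code matrix (cells x loci), binary view.
#' @param errors An [error_model()]; `model_id` in `config` overrides its
#'   `learn_fnr` flag and the cell filter.
#' @param config An [mcmc_config()].
#' @param constraints Optional integer matrix (rows of `c(ancestor_event,
#'   descendant_event)`) restricting the search to trees where the first
#'   event is a proper ancestor of the second (used for zygosity ordering).
#' @param record_states Store every thinned tree (needed for posterior
#'   summaries and attachment; default TRUE).
#' @return A `tree_posterior` list: `map_tree`, `map_loglik`, `parents`
#'   (draws x events), `beta` (draws x 1 or draws x events), `loglik`,
#'   acceptance rates, split-chain `rhat`, plus the inputs needed for
#'   attachment.
#' @export
mcmc_infer <- function(genotypes, errors, config = mcmc_config(),
                       constraints = NULL, record_states = TRUE) {
  if (nrow(genotypes) == 0L) stop("empty genotype matrix")
  check_binary_view(genotypes)

  model_id <- config$model_id
  if (!is.null(model_id)) {
    errors$learn_fnr <- model_id %in% c(1L, 3L)
    if (model_id %in% c(3L, 4L)) {
      complete <- rowSums(genotypes == 3L) == 0L
      if (!any(complete))
        stop("models 3/4 need at least one cell with a complete genotype")
      genotypes <- genotypes[complete, , drop = FALSE]
    }
  }

  all_missing <- colSums(genotypes != 3L) == 0L
  if (any(all_missing)) {
    warning("dropping loci with all-missing genotypes: ",
            paste(colnames(genotypes)[all_missing], collapse = ", "))
    genotypes <- genotypes[, !all_missing, drop = FALSE]
  }

  n_loci <- ncol(genotypes)
  fnr <- rep_len(errors$fnr, n_loci)
  learn_mode <- if (!errors$learn_fnr && !errors$locus_specific) 0L
                else if (errors$locus_specific) 2L else 1L
  burn <- as.integer(floor(config$chain_length * config$burn_in))
  con <- if (is.null(constraints)) matrix(0L, 0L, 2L)
         else matrix(as.integer(constraints), ncol = 2L)

  cp <- collapse_patterns(genotypes)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed + k - 1L)
    chains[[k]] <- cpp_mcmc(cp$D, cp$w, errors$fpr, fnr, learn_mode,
                            errors$prior_mean, errors$prior_sd,
                            if (learn_mode == 2L) config$prop_sd_locus
                            else config$prop_sd,
                            config$chain_length, burn, config$thinning,
                            config$move_weights, config$beta_move_prob,
                            con, record_states)
  }
  best <- which.max(vapply(chains, function(ch) ch$map_loglik, 0))
  map_parent <- chains[[best]]$map_parent
  # canonical tie-break: lexicographically smallest parent vector among
  # per-chain MAPs at equal log-likelihood
  for (ch in chains) {
    if (abs(ch$map_loglik - chains[[best]]$map_loglik) < 1e-9) {
      cand <- ch$map_parent
      if (paste(cand, collapse = ",") < paste(map_parent, collapse = ","))
        map_parent <- cand
    }
  }

  loglik <- lapply(chains, function(ch) ch$loglik)
  structure(list(
    map_tree = mutation_tree(map_parent, colnames(genotypes)),
    map_loglik = chains[[best]]$map_loglik,
    parents = do.call(rbind, lapply(chains, function(ch) ch$parents)),
    beta = do.call(rbind, lapply(chains, function(ch) ch$beta)),
    loglik = unlist(loglik),
    accept_tree = mean(vapply(chains, function(ch) ch$accept_tree, 0)),
    accept_beta = mean(vapply(chains, function(ch) ch$accept_beta, 0)),
    rhat = split_chain_rhat(loglik),
    labels = colnames(genotypes) %||% paste0("m", seq_len(n_loci)),
    genotypes = genotypes, errors = errors, config = config,
    constraints = con, learn_mode = learn_mode),
    class = "tree_posterior")
}

#' @export
print.tree_posterior <- function(x, ...) {
  cat("mutation-tree posterior:", nrow(x$parents), "draws,",
      length(x$labels), "events\n")
  cat("MAP log-likelihood:", format(x$map_loglik), " (rhat ",
      format(round(x$rhat, 3)), ")\n", sep = "")
  cat("MAP tree:", tree_to_newick(x$map_tree), "\n")
  invisible(x)
}

# split-chain potential scale reduction factor on the log-likelihood trace
split_chain_rhat <- function(traces) {
  halves <- unlist(lapply(traces, function(x) {
    h <- length(x) %/% 2L
    if (h < 2L) return(NULL)
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  if (length(halves) < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Encode a zygosity genotype matrix for constrained tree search
#'
#' Loci with at least one homozygous (code 2) call are split into two event
#' columns: `<locus>` (mutation acquired: 1 iff the call is het or hom) and
#' `<locus>_loh` (loss of heterozygosity: 1 iff the call is hom). Missing
#' calls propagate to both columns. The returned constraints force the
#' mutation event to be a proper ancestor of its LOH event during MCMC, so
#' the heterozygous state of a mutation always precedes its homozygous
#' state in sampled trees.
#'
#' @param genotypes Integer code matrix with codes in `{0, 1, 2, 3}`.
#' @return List with `binary` (code matrix in `{0, 1, 3}`), `constraints`
#'   (integer matrix of ancestor/descendant event-column pairs), and
#'   `locus_map` (source locus per event column).
#' @export
encode_zygosity <- function(genotypes) {
  if (!all(genotypes %in% c(0L, 1L, 2L, 3L)))
    stop("genotype codes must be in {0, 1, 2, 3}")
  cols <- list()
  locus_map <- character(0)
  constraints <- NULL
  nm <- colnames(genotypes) %||% paste0("m", seq_len(ncol(genotypes)))
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    m <- ifelse(g == 3L, 3L, as.integer(g %in% c(1L, 2L)))
    cols[[length(cols) + 1L]] <- m
    names(cols)[length(cols)] <- nm[j]
    locus_map <- c(locus_map, nm[j])
    if (any(g == 2L)) {
      l <- ifelse(g == 3L, 3L, as.integer(g == 2L))
      cols[[length(cols) + 1L]] <- l
      names(cols)[length(cols)] <- paste0(nm[j], "_loh")
      locus_map <- c(locus_map, nm[j])
      constraints <- rbind(constraints,
                           c(length(cols) - 1L, length(cols)))
    }
  }
  binary <- do.call(cbind, cols)
  rownames(binary) <- rownames(genotypes)
  list(binary = binary,
       constraints = if (is.null(constraints)) matrix(0L, 0L, 2L)
                     else constraints,
       locus_map = locus_map)
}

#' Posterior cell-to-subclone attachment
#'
#' For each posterior draw (tree and error rates), cells are assigned to
#' tree nodes jointly with a latent clonal composition: a short Gibbs chain
#' alternates between sampling each cell's node with probability
#' proportional to `pi[v] * P(D_c | node v)` and resampling the
#' per-timepoint composition `pi ~ Dirichlet(1 + counts)`. Subclone sizes
#' per draw are the assigned-cell counts, summarized as the posterior mean
#' and a 95% credible interval. (A flat attachment prior in place of the
#' learned composition would bias subclone sizes by roughly the dropout
#' rate toward descendant clones; the latent composition removes that
#' bias.) When `timepoints` are given, a cell from timepoint `t` gets zero
#' probability at any node at or below an event unobserved at `t`.
#'
#' @param posterior A `tree_posterior` from [mcmc_infer()].
#' @param genotypes Genotype matrix to attach (default: the matrix used for
#'   inference).
#' @param timepoints Optional timepoint label per cell.
#' @param max_draws Subsample at most this many posterior draws.
#' @param sweeps Gibbs sweeps per posterior draw.
#' @param seed Integer seed for the assignment sampler.
#' @return An `attachment_posterior` list: `prob` (cells x nodes posterior
#'   mean attachment), `node_labels`, per-timepoint `summary` data frames
#'   (node, point estimate, CI bounds, counts), the raw per-draw `counts`,
#'   and `flagged_cells` (all-missing genotypes, attached by the learned
#'   composition alone).
#' @export
attach_cells <- function(posterior, genotypes = NULL, timepoints = NULL,
                         max_draws = 500L, sweeps = 20L, seed = 1L) {
  if (nrow(posterior$parents) == 0L)
    stop("posterior has no recorded tree draws")
  if (is.null(genotypes)) genotypes <- posterior$genotypes
  check_binary_view(genotypes)
  J <- length(posterior$labels)
  cp <- collapse_patterns(genotypes, timepoints)
  n_tp <- length(cp$tp_levels)
  observed <- matrix(1L, n_tp, J)
  if (!is.null(timepoints)) {
    observed <- observed_events(genotypes, timepoints)
  }
  draws <- nrow(posterior$parents)
  keep <- if (draws > max_draws)
    unique(round(seq(1L, draws, length.out = max_draws))) else seq_len(draws)
  set.seed(seed)
  res <- cpp_attach(cp$D, cp$w, posterior$errors$fpr,
                    posterior$parents[keep, , drop = FALSE],
                    posterior$beta[keep, , drop = FALSE],
                    observed, cp$tp - 1L, as.integer(sweeps))
  node_labels <- c("root", posterior$labels)
  prob <- res$mean_prob[cp$cell_pattern, , drop = FALSE]
  dimnames(prob) <- list(rownames(genotypes), node_labels)
  counts <- array(res$counts, dim = c(length(keep), J + 1L, n_tp),
                  dimnames = list(NULL, node_labels, cp$tp_levels))
  summaries <- lapply(seq_len(n_tp), function(t) {
    cnt <- counts[, , t, drop = FALSE][, , 1L]
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = length(keep))
    mutated <- rowSums(cnt[, -1L, drop = FALSE])
    frac <- cnt[, -1L, drop = FALSE] / ifelse(mutated > 0, mutated, NA)
    data.frame(node = node_labels[-1L],
               mean_count = colMeans(cnt)[-1L],
               mean_fraction = colMeans(frac, na.rm = TRUE),
               ci_lower = apply(frac, 2L, stats::quantile, 0.025,
                                na.rm = TRUE, names = FALSE),
               ci_upper = apply(frac, 2L, stats::quantile, 0.975,
                                na.rm = TRUE, names = FALSE),
               row.names = NULL)
  })
  names(summaries) <- cp$tp_levels
  flagged <- which(rowSums(genotypes != 3L) == 0L)
  structure(list(prob = prob, node_labels = node_labels, counts = counts,
                 summary = summaries, tree = posterior$map_tree,
                 timepoints = cp$tp_levels, cell_tp = cp$tp[cp$cell_pattern],
                 flagged_cells = flagged),
            class = "attachment_posterior")
}

# which mutations were observed (at least one mutant call) per timepoint
observed_events <- function(genotypes, timepoints) {
  tps <- levels(factor(timepoints))
  t(vapply(tps, function(t)
    as.integer(colSums(genotypes[timepoints == t, , drop = FALSE] == 1L) > 0L),
    integer(ncol(genotypes))))
}

#' Joint inference across longitudinal timepoints
#'
#' Pools the genotype matrices of all timepoints, infers one mutation tree
#' from the pooled data, and attaches cells per timepoint with the
#' restriction that a cell cannot be placed at or below any mutation
#' unobserved at its sampling time. A subclone can consequently have a
#' prevalence of 0% at a timepoint without implying extinction.
#'
#' @param genotype_list Named list of genotype matrices (one per timepoint)
#'   sharing a locus panel.
#' @param errors An [error_model()].
#' @param config An [mcmc_config()].
#' @return List with `posterior` (pooled `tree_posterior`) and `attachment`
#'   (per-timepoint `attachment_posterior`).
#' @export
longitudinal_infer <- function(genotype_list, errors, config = mcmc_config()) {
  if (length(genotype_list) < 2L) stop("need at least two timepoints")
  panels <- lapply(genotype_list, colnames)
  if (!all(vapply(panels[-1L], identical, TRUE, panels[[1L]])))
    stop("timepoints must share a locus panel")
  if (is.null(names(genotype_list)))
    names(genotype_list) <- paste0("t", seq_along(genotype_list))
  pooled <- do.call(rbind, genotype_list)
  tp <- rep(names(genotype_list), vapply(genotype_list, nrow, 0L))
  posterior <- mcmc_infer(pooled, errors, config)
  attachment <- attach_cells(posterior, pooled, timepoints = tp)
  list(posterior = posterior, attachment = attachment)
}

#' Compare the four standard model configurations
#'
#' Runs models 1-4 on the same genotype matrix and reports pairwise MAP
#' parent-vector agreement. The run is flagged `consistent` iff all four
#' MAP parent vectors are identical.
#'
#' @param genotypes Genotype matrix (binary view).
#' @param errors An [error_model()].
#' @param config An [mcmc_config()]; `model_id` is overridden per run.
#' @return List with `map_parents` (4 x events), `pairwise` (6-row data
#'   frame of agreement fractions), and `consistent`.
#' @export
consensus_across_models <- function(genotypes, errors,
                                    config = mcmc_config()) {
  maps <- matrix(NA_integer_, 4L, ncol(genotypes))
  for (m in 1:4) {
    cfg <- config
    cfg$model_id <- m
    fit <- mcmc_infer(genotypes, errors, cfg, record_states = FALSE)
    maps[m, ] <- fit$map_tree$parent
  }
  pairs <- utils::combn(4L, 2L)
  pw <- data.frame(model_a = pairs[1L, ], model_b = pairs[2L, ],
                   agreement = apply(pairs, 2L, function(p)
                     mean(maps[p[1L], ] == maps[p[2L], ])))
  list(map_parents = maps, pairwise = pw,
       consistent = all(pw$agreement == 1))
}

#' Write an attachment probability matrix as TSV
#'
#' @param attachment An `attachment_posterior`.
#' @param path Output file.
#' @export
write_attachment_tsv <- function(attachment, path) {
  df <- data.frame(cell_id = rownames(attachment$prob) %||%
                     paste0("cell", seq_len(nrow(attachment$prob))),
                   attachment$prob, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
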