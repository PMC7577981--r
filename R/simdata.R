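#' Simulate a random mutation tree
#'
#' Draws a random recursive tree: events are placed one at a time and each
#' new event's parent is chosen uniformly from the root and all previously
#' placed events. For two events this gives the fork with probability 1/2
#' and each of the two chains with probability 1/4.
#'
#' @param n_mutations Number of mutation events (>= 1).
#' @param seed Integer seed.
#' @param labels Optional event labels.
#' @return A [mutation_tree()].
#' @export
simulate_tree <- function(n_mutations, seed, labels = NULL) {
  if (!is.numeric(n_mutations) || n_mutations < 1)
    stop("n_mutations must be a positive integer")
  n_mutations <- as.integer(n_mutations)
  set.seed(seed)
  pos_parent <- integer(n_mutations)
  for (j in seq_len(n_mutations)) {
    # uniform over {root(0), positions 1, ..., j-1}
    pos_parent[j] <- sample.int(j, 1L) - 1L
  }
  # assign event labels to insertion positions uniformly at random so the
  # law is exchangeable in the labels (insertion order alone would force
  # parent[j] < j)
  lab <- sample.int(n_mutations)
  parent <- integer(n_mutations)
  for (j in seq_len(n_mutations)) {
    p <- pos_parent[j]
    parent[lab[j]] <- if (p == 0L) 0L else lab[p]
  }
  mutation_tree(parent, labels)
}

#' Simulate clone fractions on a tree, optionally over timepoints
#'
#' Mutated-node fractions are a symmetric Dirichlet draw rescaled to
#' `1 - wt_fraction`; the root (wild-type) clone receives `wt_fraction`.
#' Successive timepoints are perturbed by logistic-normal noise: log
#' fractions receive independent Gaussian noise of standard deviation
#' `drift` and are renormalized, so `drift = 0` reproduces the first
#' timepoint exactly.
#'
#' @param tree A `mutation_tree`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration (> 0).
#' @param wt_fraction Fraction of wild-type (root) cells, in `[0, 1)`.
#' @param n_timepoints Number of timepoints (>= 1).
#' @param drift Logistic-normal drift scale between timepoints (>= 0).
#' @param depth_decay Expected clone size multiplier per tree depth level,
#'   in `(0, 1]`. Values below 1 make deeper (younger) clones smaller in
#'   expectation, emulating that recently arisen subclones have had less
#'   time to expand; 1 (default) treats all clones symmetrically.
#' @param seed Integer seed.
#' @return Matrix `(n_events + 1) x n_timepoints` of fractions; row 1 is the
#'   root. Each column sums to 1.
#' @export
simulate_clone_fractions <- function(tree, dirichlet_alpha = 1,
                                     wt_fraction = 0.1, n_timepoints = 1L,
                                     drift = 0, depth_decay = 1, seed = 1L) {
  if (wt_fraction < 0 || wt_fraction >= 1)
    stop("wt_fraction must be in [0, 1)")
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be positive")
  if (drift < 0) stop("drift must be non-negative")
  if (depth_decay <= 0 || depth_decay > 1)
    stop("depth_decay must be in (0, 1]")
  set.seed(seed)
  n <- length(tree$parent)
  g <- stats::rgamma(n, shape = dirichlet_alpha)
  if (depth_decay < 1) {
    depth <- vapply(seq_len(n), function(j) {
      d <- 0L
      while (j != 0L) { j <- tree$parent[j]; d <- d + 1L }
      d
    }, 0L)
    g <- g * depth_decay^depth
  }
  mut <- g / sum(g) * (1 - wt_fraction)
  f <- matrix(0, n + 1L, n_timepoints)
  f[, 1L] <- c(wt_fraction, mut)
  if (n_timepoints > 1L) {
    for (t in 2:n_timepoints) {
      if (drift == 0) {
        f[, t] <- f[, t - 1L]
      } else {
        lg <- log(pmax(f[, t - 1L], 1e-12)) + stats::rnorm(n + 1L, 0, drift)
        x <- exp(lg - max(lg))
        f[, t] <- x / sum(x)
      }
    }
  }
  rownames(f) <- c("root", tree$labels)
  colnames(f) <- paste0("t", seq_len(n_timepoints))
  f
}

#' Generate true per-cell genotypes from a clonal tree
#'
#' Cells are assigned to tree nodes multinomially by the clone fractions.
#' A cell's genotype at locus `j` is heterozygous (1) if the mutation event
#' of `j` is an ancestor-or-self of its node and the corresponding LOH event
#' (if any) is not; homozygous (2) if the LOH event is ancestor-or-self;
#' otherwise wild type (0).
#'
#' @param tree A `mutation_tree` whose events are the het mutation events.
#' @param fractions Vector over `n_events + 1` nodes (root first) or a
#'   single column of [simulate_clone_fractions()].
#' @param n_cells Number of cells.
#' @param loh_events Optional list of `list(locus =, node =)` entries: the
#'   LOH of `locus` arises at tree node `node`, which must be a proper
#'   descendant of the node carrying the het event of `locus`.
#' @param seed Integer seed.
#' @return List with `genotypes` (integer matrix cells x loci, codes 0/1/2),
#'   `node` (attachment node per cell, 0 = root).
#' @export
genotypes_from_tree <- function(tree, fractions, n_cells, loh_events = list(),
                                seed = 1L) {
  set.seed(seed)
  n <- length(tree$parent)
  fractions <- as.numeric(fractions)
  if (length(fractions) != n + 1L)
    stop("fractions must cover the root and every event")
  for (ev in loh_events) {
    if (!is_ancestor(tree, ev$locus, ev$node, proper = TRUE))
      stop("LOH node must be a proper descendant of its het event")
  }
  A <- ancestor_matrix(tree)
  node <- sample.int(n + 1L, n_cells, replace = TRUE, prob = fractions) - 1L
  G <- matrix(0L, n_cells, n, dimnames = list(NULL, tree$labels))
  for (j in seq_len(n)) G[, j] <- as.integer(A[node + 1L, j])
  for (ev in loh_events) {
    hom <- A[node + 1L, ev$node]
    G[hom, ev$locus] <- 2L
  }
  list(genotypes = G, node = node)
}

#' Add observation noise to a true genotype matrix
#'
#' In binary mode each true 0 flips to 1 with probability `fpr`, each true 1
#' flips to 0 with the locus false-negative rate `fnr[j]`, and entries are
#' then set to missing (3) with probability `missing_rate[j]`. With
#' probability `doublet_rate` a cell's true row is first replaced by the
#' elementwise maximum of its own and another random cell's true genotypes
#' (a multiplet looks mutant wherever either cell is).
#'
#' In zygosity mode (matrices containing code 2) the false-negative process
#' models single-allele dropout: a true het is observed as wild type or as
#' homozygous with probability `fnr[j]/2` each, and a true hom is observed
#' as het with probability `fnr[j]/2`.
#'
#' @param genotypes Integer matrix of codes 0/1 (binary) or 0/1/2.
#' @param fpr False-positive rate.
#' @param fnr Scalar or per-locus false-negative (allele-dropout) rate.
#' @param missing_rate Scalar or per-locus missing probability.
#' @param doublet_rate Probability a cell is a doublet.
#' @param seed Integer seed.
#' @return Integer matrix with codes 0/1(/2)/3.
#' @export
add_observation_noise <- function(genotypes, fpr = 0.01, fnr = 0.058,
                                  missing_rate = 0, doublet_rate = 0,
                                  seed = 1L) {
  rates <- c(fpr, fnr, missing_rate, doublet_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  set.seed(seed)
  n_cells <- nrow(genotypes)
  n_loci <- ncol(genotypes)
  fnr <- rep_len(fnr, n_loci)
  missing_rate <- rep_len(missing_rate, n_loci)
  G <- genotypes
  if (doublet_rate > 0 && n_cells > 1L) {
    is_dbl <- stats::runif(n_cells) < doublet_rate
    partner <- sample.int(n_cells, n_cells, replace = TRUE)
    for (i in which(is_dbl)) G[i, ] <- pmax(genotypes[i, ], genotypes[partner[i], ])
  }
  obs <- G
  zygosity <- any(G == 2L)
  for (j in seq_len(n_loci)) {
    u <- stats::runif(n_cells)
    if (zygosity) {
      het <- G[, j] == 1L
      hom <- G[, j] == 2L
      obs[het & u < fnr[j] / 2, j] <- 0L
      obs[het & u >= fnr[j] / 2 & u < fnr[j], j] <- 2L
      obs[hom & u < fnr[j] / 2, j] <- 1L
    } else {
      obs[G[, j] == 1L & u < fnr[j], j] <- 0L
    }
    obs[G[, j] == 0L & u < fpr, j] <- 1L
    miss <- stats::runif(n_cells) < missing_rate[j]
    obs[miss, j] <- 3L
  }
  obs
}

#' Simulate per-cell read counts from true genotypes
#'
#' Depth is negative-binomial with the given mean and dispersion (`size`
#' parameter of [stats::rnbinom()]). For a true heterozygous cell each of
#' the two alleles independently fails to amplify with per-allele
#' probability `q = (1 - sqrt(1 - 2 * ado)) / 2`, chosen so that the
#' probability of a homozygous-looking cell (exactly one allele dropped,
#' `2 q (1 - q)`) equals `ado`; when both alleles drop the cell yields no
#' reads at the locus. The alternate-read count is binomial with success
#' probability 0.5 (het, both alleles present), `1 - base_error` (hom, or
#' het with the reference allele dropped), or `base_error` (wild type, or
#' het with the alternate allele dropped).
#'
#' @param genotypes Integer matrix of true codes 0/1/2 (cells x loci).
#' @param mean_depth Mean sequencing depth per cell per amplicon.
#' @param depth_dispersion Negative-binomial `size`; larger is less
#'   overdispersed.
#' @param ado Scalar or per-locus allele-dropout rate (< 0.5).
#' @param base_error Per-read error probability.
#' @param seed Integer seed.
#' @return List of integer matrices `depth` and `alt` (cells x loci).
#' @export
simulate_read_counts <- function(genotypes, mean_depth = 48,
                                 depth_dispersion = 4, ado = 0.058,
                                 base_error = 0.005, seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (any(ado < 0 | ado >= 0.5)) stop("ado must be in [0, 0.5)")
  set.seed(seed)
  n_cells <- nrow(genotypes)
  n_loci <- ncol(genotypes)
  ado <- rep_len(ado, n_loci)
  q <- (1 - sqrt(1 - 2 * ado)) / 2  # per-allele dropout
  depth <- matrix(stats::rnbinom(n_cells * n_loci, size = depth_dispersion,
                                 mu = mean_depth),
                  n_cells, n_loci)
  alt <- matrix(0L, n_cells, n_loci, dimnames = dimnames(genotypes))
  for (j in seq_len(n_loci)) {
    g <- genotypes[, j]
    p_alt <- ifelse(g == 0L, base_error, 1 - base_error)
    het <- g == 1L
    if (any(het)) {
      drop_ref <- stats::runif(n_cells) < q[j]
      drop_alt <- stats::runif(n_cells) < q[j]
      p_alt[het & !drop_ref & !drop_alt] <- 0.5
      p_alt[het & drop_ref & !drop_alt] <- 1 - base_error
      p_alt[het & !drop_ref & drop_alt] <- base_error
      both <- het & drop_ref & drop_alt
      depth[both, j] <- 0L
    }
    alt[, j] <- stats::rbinom(n_cells, depth[, j], p_alt)
  }
  list(depth = depth, alt = alt)
}

#' Simulate a complete single-cell DNA-seq sample
#'
#' Bundles tree, clone-fraction, genotype, and read-count simulation with
#' defaults mirroring a targeted AML panel run: ~6,000 cells, allele
#' dropout 5.8%, false-positive rate 1%, mean amplicon depth 48x, plus a
#' set of germline heterozygous SNP loci used downstream for allele-dropout
#' estimation.
#'
#' @param n_mutations Number of somatic driver events.
#' @param n_cells Cells per timepoint.
#' @param n_snps Germline heterozygous SNP loci (all cells truly het).
#' @param ado Allele-dropout rate.
#' @param fpr Genotype-level false-positive rate.
#' @param missing_rate Per-locus missing probability for genotype-level
#'   output.
#' @param doublet_rate Doublet probability.
#' @param wt_fraction Wild-type cell fraction.
#' @param dirichlet_alpha Clone-fraction concentration.
#' @param n_timepoints Number of timepoints.
#' @param drift Clone-fraction drift between timepoints.
#' @param mean_depth,depth_dispersion,base_error Read-count parameters.
#' @param seed Integer seed.
#' @return List with `truth` (tree, fractions, nodes per timepoint, rates,
#'   seed), `genotypes` (observed codes per timepoint, cells x loci),
#'   `reads` (depth/alt matrices including SNP loci), and `locus_class`.
#' @export
simulate_sample <- function(n_mutations = 8, n_cells = 6000, n_snps = 10,
                            ado = 0.058, fpr = 0.01, missing_rate = 0,
                            doublet_rate = 0, wt_fraction = 0.1,
                            dirichlet_alpha = 1.5, n_timepoints = 1L,
                            drift = 0, mean_depth = 48, depth_dispersion = 4,
                            base_error = 0.005, seed = 1L) {
  tree <- simulate_tree(n_mutations, seed = seed)
  fr <- simulate_clone_fractions(tree, dirichlet_alpha, wt_fraction,
                                 n_timepoints, drift, seed = seed + 1L)
  genotypes <- vector("list", n_timepoints)
  reads <- vector("list", n_timepoints)
  nodes <- vector("list", n_timepoints)
  for (t in seq_len(n_timepoints)) {
    gt <- genotypes_from_tree(tree, fr[, t], n_cells, seed = seed + 10L * t)
    true_full <- cbind(gt$genotypes,
                       matrix(1L, n_cells, n_snps,
                              dimnames = list(NULL, paste0("snp", seq_len(n_snps)))))
    reads[[t]] <- simulate_read_counts(true_full, mean_depth, depth_dispersion,
                                       ado, base_error, seed = seed + 10L * t + 1L)
    genotypes[[t]] <- add_observation_noise(gt$genotypes, fpr, ado,
                                            missing_rate, doublet_rate,
                                            seed = seed + 10L * t + 2L)
    rownames(genotypes[[t]]) <- paste0("t", t, "_cell", seq_len(n_cells))
    rownames(reads[[t]]$depth) <- rownames(reads[[t]]$alt) <-
      rownames(genotypes[[t]])
    nodes[[t]] <- gt$node
  }
  list(truth = list(tree = tree, clone_fractions = fr, node = nodes,
                    error_params = list(fpr = fpr, fnr = ado,
                                        missing_rate = missing_rate,
                                        doublet_rate = doublet_rate),
                    seed = seed),
       genotypes = genotypes, reads = reads,
       locus_class = c(rep("somatic", n_mutations), rep("snp", n_snps)))
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of [simulate_sample()].
#' @param path Output file.
#' @export
write_simulation_truth <- function(truth, path) {
  obj <- list(parent = truth$tree$parent, labels = truth$tree$labels,
              clone_fractions = truth$clone_fractions,
              error_params = truth$error_params, seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
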