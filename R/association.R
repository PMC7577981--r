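#' Haldane-corrected log odds ratio of a 2x2 table
#'
#' Adds 0.5 to every cell so the odds ratio is finite for tables with
#' zeros.
#'
#' @param a,b,c,d Table counts: `a` = both present, `b` = first only,
#'   `c` = second only, `d` = neither.
#' @param base Logarithm base (2 for cell-level results, `exp(1)` for
#'   cohort-level).
#' @return Log odds ratio.
#' @export
haldane_log_or <- function(a, b, c, d, base = 2) {
  log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)), base = base)
}

#' G-test of independence for a 2x2 table
#'
#' \eqn{G = 2 \sum O \ln(O/E)} on the uncorrected counts (with the
#' convention \eqn{0 \ln(0/E) = 0}), expected counts from the margins, and
#' the p value from the chi-squared distribution with one degree of
#' freedom.
#'
#' @param a,b,c,d Table counts.
#' @return List with `G` and `p`.
#' @export
g_test <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  if (n == 0) return(list(G = NA_real_, p = NA_real_))
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  terms <- ifelse(o > 0, o * log(o / e), 0)
  G <- 2 * sum(terms)
  list(G = G, p = stats::pchisq(G, df = 1L, lower.tail = FALSE))
}

pair_table <- function(x, y) {
  c(a = sum(x & y), b = sum(x & !y), c = sum(!x & y), d = sum(!x & !y))
}

#' Cell-level mutation co-occurrence within a sample
#'
#' For every locus pair, cells missing at either locus are excluded, a 2x2
#' mutant/wild-type table is built, the log2 odds ratio is computed with
#' Haldane correction, significance comes from a two-sided Fisher exact
#' test, and Benjamini-Hochberg q values are computed across all pairs of
#' the sample. Pairs with no informative cells are flagged (`NA` p value)
#' and excluded from the multiple-testing adjustment.
#'
#' @param genotypes Genotype code matrix; codes 1 and 2 count as mutant,
#'   3 as missing.
#' @return data.frame with columns pair_a, pair_b, a, b, c, d, log_or,
#'   base, p, q, level.
#' @export
cell_cooccurrence <- function(genotypes) {
  if (ncol(genotypes) < 2L) stop("need at least two loci")
  nm <- colnames(genotypes) %||% paste0("m", seq_len(ncol(genotypes)))
  pairs <- utils::combn(ncol(genotypes), 2L)
  res <- apply(pairs, 2L, function(pr) {
    gi <- genotypes[, pr[1L]]
    gj <- genotypes[, pr[2L]]
    ok <- gi != 3L & gj != 3L
    if (!any(ok)) return(c(NA, NA, NA, NA, NA, NA))
    tb <- pair_table(gi[ok] %in% c(1L, 2L), gj[ok] %in% c(1L, 2L))
    p <- stats::fisher.test(matrix(tb[c("a", "b", "c", "d")], 2L,
                                   byrow = TRUE))$p.value
    c(tb, log_or = haldane_log_or(tb["a"], tb["b"], tb["c"], tb["d"],
                                  base = 2),
      p = p)
  })
  out <- data.frame(pair_a = nm[pairs[1L, ]], pair_b = nm[pairs[2L, ]],
                    a = res[1L, ], b = res[2L, ], c = res[3L, ],
                    d = res[4L, ], log_or = res[5L, ], base = 2,
                    p = res[6L, ], q = NA_real_, level = "cell")
  out$q[!is.na(out$p)] <- stats::p.adjust(out$p[!is.na(out$p)], "BH")
  out
}

cohort_pairwise <- function(presence, level) {
  nm <- colnames(presence)
  keep <- colSums(presence) > 0L
  if (any(!keep)) {
    warning("excluding genes absent from every unit: ",
            paste(nm[!keep], collapse = ", "))
    presence <- presence[, keep, drop = FALSE]
    nm <- nm[keep]
  }
  if (ncol(presence) < 2L) stop("need at least two genes with occurrences")
  pairs <- utils::combn(ncol(presence), 2L)
  res <- apply(pairs, 2L, function(pr) {
    tb <- pair_table(presence[, pr[1L]], presence[, pr[2L]])
    gt <- g_test(tb["a"], tb["b"], tb["c"], tb["d"])
    c(tb, log_or = haldane_log_or(tb["a"], tb["b"], tb["c"], tb["d"],
                                  base = exp(1)),
      G = gt$G, p = gt$p)
  })
  out <- data.frame(pair_a = nm[pairs[1L, ]], pair_b = nm[pairs[2L, ]],
                    a = res[1L, ], b = res[2L, ], c = res[3L, ],
                    d = res[4L, ], log_or = res[5L, ], base = exp(1),
                    G = res[6L, ], p = res[7L, ], q = NA_real_,
                    level = level)
  out$q[!is.na(out$p)] <- stats::p.adjust(out$p[!is.na(out$p)], "BH")
  out
}

#' Cohort-level co-occurrence from per-patient mutation presence
#'
#' For each gene pair, the per-patient presence/absence contingency table
#' is summarized by the Haldane-corrected (natural) log odds ratio, tested
#' for independence with a G-test against the chi-squared distribution, and
#' adjusted with Benjamini-Hochberg across pairs.
#'
#' @param presence Logical/0-1 matrix, patients x genes.
#' @return data.frame as in [cell_cooccurrence()] plus a `G` column.
#' @export
bulk_cooccurrence <- function(presence) {
  if (nrow(presence) < 2L || ncol(presence) < 2L)
    stop("need at least two patients and two genes")
  cohort_pairwise(presence > 0, "patient_bulk")
}

#' Clone-level co-occurrence pooled across samples
#'
#' Units are clones pooled across patients, restricted to clones comprising
#' at least `min_fraction` of a patient's mutated (tumor) cells; a gene is
#' present in a clone when any of its events is in the clone's mutation
#' set. Statistics as in [bulk_cooccurrence()].
#'
#' @param compositions List of `clonal_composition` objects (or per-sample
#'   subclone data frames with `mutations` and `fraction` columns).
#' @param min_fraction Clone-size threshold (default 0.01).
#' @param genes Optional map from event label to gene (defaults to the
#'   label stripped of a trailing `_<suffix>`).
#' @return data.frame as in [bulk_cooccurrence()], `level = "clone"`.
#' @export
clone_cooccurrence <- function(compositions, min_fraction = 0.01,
                               genes = NULL) {
  clone_sets <- list()
  for (comp in compositions) {
    dfs <- if (inherits(comp, "clonal_composition")) comp$subclones
           else list(comp)
    for (df in dfs) {
      if (NROW(df) == 0L) next
      df <- df[df$fraction >= min_fraction, , drop = FALSE]
      clone_sets <- c(clone_sets, strsplit(df$mutations, ","))
    }
  }
  if (length(clone_sets) == 0L)
    return(data.frame(pair_a = character(0), pair_b = character(0),
                      a = numeric(0), b = numeric(0), c = numeric(0),
                      d = numeric(0), log_or = numeric(0), base = numeric(0),
                      G = numeric(0), p = numeric(0), q = numeric(0),
                      level = character(0)))
  map_gene <- function(ev) {
    if (is.null(genes)) sub("_[^_]*$", "", ev) else unname(genes[ev])
  }
  gene_sets <- lapply(clone_sets, function(s) unique(map_gene(s)))
  all_genes <- sort(unique(unlist(gene_sets)))
  presence <- t(vapply(gene_sets, function(s) all_genes %in% s,
                       logical(length(all_genes))))
  colnames(presence) <- all_genes
  if (ncol(presence) < 2L) stop("need at least two genes across clones")
  cohort_pairwise(presence, "clone")
}

#' Write pairwise association results
#'
#' Long-format TSV plus an optional square log-OR matrix.
#'
#' @param results data.frame from one of the co-occurrence functions.
#' @param path Long-format TSV path.
#' @param matrix_path Optional square-matrix TSV path.
#' @export
write_cooccurrence_tsv <- function(results, path, matrix_path = NULL) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(matrix_path)) {
    units <- sort(unique(c(results$pair_a, results$pair_b)))
    m <- matrix(NA_real_, length(units), length(units),
                dimnames = list(units, units))
    diag(m) <- 0
    for (r in seq_len(nrow(results))) {
      m[results$pair_a[r], results$pair_b[r]] <- results$log_or[r]
      m[results$pair_b[r], results$pair_a[r]] <- results$log_or[r]
    }
    utils::write.table(data.frame(unit = units, m, check.names = FALSE),
                       matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
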