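#' Derive the clonal composition from an attachment posterior
#'
#' A subclone is a tree node carrying at least one mutation with at least
#' one assigned cell (cells are hard-assigned to their maximum-probability
#' node). Its mutation set is the set of events on the node's root path;
#' its fraction is its cell count over all mutated cells (wild-type cells,
#' assigned to the root, are excluded). Subclones below `threshold` are
#' retained but flagged, and downstream association analyses exclude them.
#' Credible intervals on the fractions come from the posterior draws.
#'
#' @param attachment An `attachment_posterior` from [attach_cells()].
#' @param threshold Minimum fraction of mutated cells for an unflagged
#'   clone (default 0.01).
#' @return A `clonal_composition`: list of per-timepoint data frames
#'   (`clone`, `mutations`, `n_cells`, `fraction`, `ci_lower`, `ci_upper`,
#'   `below_threshold`), plus `wt_cell_count` per timepoint and the tree.
#' @export
compose_clones <- function(attachment, threshold = 0.01) {
  tree <- attachment$tree
  A <- ancestor_matrix(tree)
  labels <- attachment$node_labels
  assigned <- max.col(attachment$prob, ties.method = "first")  # 1 = root
  tps <- attachment$timepoints
  per_tp <- vector("list", length(tps))
  wt <- integer(length(tps))
  for (t in seq_along(tps)) {
    nodes <- assigned[attachment$cell_tp == t]
    cnt <- tabulate(nodes, nbins = length(labels))
    wt[t] <- cnt[1L]
    mutated <- sum(cnt[-1L])
    if (mutated == 0L) {
      per_tp[[t]] <- data.frame(clone = character(0), mutations = character(0),
                                n_cells = integer(0), fraction = numeric(0),
                                ci_lower = numeric(0), ci_upper = numeric(0),
                                below_threshold = logical(0))
      next
    }
    keep <- which(cnt[-1L] > 0L)  # event-node indices with >= 1 cell
    ci <- attachment$summary[[t]]
    # counts are hard assignments (cells are conserved exactly); fractions
    # are the posterior means, consistent with the credible intervals
    per_tp[[t]] <- data.frame(
      clone = labels[keep + 1L],
      mutations = vapply(keep, function(v)
        paste(tree$labels[A[v + 1L, ]], collapse = ","), ""),
      n_cells = cnt[keep + 1L],
      fraction = ci$mean_fraction[keep],
      ci_lower = ci$ci_lower[keep],
      ci_upper = ci$ci_upper[keep],
      below_threshold = ci$mean_fraction[keep] < threshold,
      row.names = NULL)
  }
  names(per_tp) <- tps
  structure(list(subclones = per_tp, wt_cell_count = stats::setNames(wt, tps),
                 tree = tree, threshold = threshold),
            class = "clonal_composition")
}

#' @export
print.clonal_composition <- function(x, ...) {
  for (t in names(x$subclones)) {
    cat("timepoint", t, "-", nrow(x$subclones[[t]]), "subclones,",
        x$wt_cell_count[[t]], "wild-type cells\n")
    print(x$subclones[[t]], ...)
  }
  invisible(x)
}

#' Shannon diversity of a clonal composition
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the mutated-subclone fractions,
#' renormalized to sum to one. Wild-type cells are excluded, consistent
#' with the subclone definition; set `include_wt = TRUE` to fold them in as
#' an extra class for sensitivity analysis.
#'
#' @param composition A `clonal_composition`, a per-timepoint subclone data
#'   frame, or a bare numeric vector of clone sizes/fractions.
#' @param timepoint Which timepoint to use (default first).
#' @param include_wt Include the wild-type cells as a class.
#' @return Shannon index in bits.
#' @export
shannon_index <- function(composition, timepoint = 1L, include_wt = FALSE) {
  if (is.numeric(composition)) {
    p <- composition
  } else {
    df <- if (inherits(composition, "clonal_composition"))
      composition$subclones[[timepoint]] else composition
    if (NROW(df) == 0L) stop("empty clonal composition")
    p <- df$n_cells
    if (include_wt && inherits(composition, "clonal_composition"))
      p <- c(p, composition$wt_cell_count[[timepoint]])
  }
  p <- p[p > 0]
  if (length(p) == 0L) stop("no clones with positive size")
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Classify the clonal evolution pattern of a tree
#'
#' The event tree is first restricted to events carried by at least one
#' surviving subclone (fraction at or above the composition threshold, when
#' a composition is supplied). The pattern is `linear` when the restricted
#' tree has no branch point, or exactly one branch point all of whose
#' children are leaf events (a terminal fork, counted as linear;
#' `terminal_fork_linear = FALSE` switches to the strict pure-path rule).
#' Otherwise the pattern is `branching`. A branching case is additionally
#' called convergent when two events mapping to the same gene (or the same
#' pathway, when a `pathway_map` is supplied) occur on disjoint branches,
#' i.e. neither is an ancestor of the other.
#'
#' @param tree A `mutation_tree`.
#' @param composition Optional `clonal_composition` used to restrict the
#'   tree to surviving events.
#' @param genes Named character vector mapping event labels to genes;
#'   defaults to the event label stripped of a trailing `_<suffix>` (so
#'   `FLT3_a`, `FLT3_b` map to the same gene).
#' @param pathway_map Optional named character vector mapping genes to
#'   pathways; when given, convergence is assessed at the pathway level.
#' @param terminal_fork_linear Count a single terminal fork as linear.
#' @param timepoint Composition timepoint used for survival (default 1).
#' @return An `evolution_call` list: `pattern` (`"linear"`/`"branching"`),
#'   `convergent`, `branch_points`, `convergent_events`.
#' @export
classify_evolution <- function(tree, composition = NULL, genes = NULL,
                               pathway_map = NULL,
                               terminal_fork_linear = TRUE, timepoint = 1L) {
  n <- length(tree$parent)
  if (n < 1L) stop("tree must have at least one event")
  surviving <- rep(TRUE, n)
  if (!is.null(composition)) {
    df <- composition$subclones[[timepoint]]
    df <- df[!df$below_threshold, , drop = FALSE]
    surviving <- rep(FALSE, n)
    A <- ancestor_matrix(tree)
    nodes <- match(df$clone, tree$labels)
    for (v in nodes) surviving <- surviving | A[v + 1L, ]
  }
  events <- which(surviving)
  if (length(events) == 0L)
    return(structure(list(pattern = "linear", convergent = FALSE,
                          branch_points = character(0),
                          convergent_events = list()),
                     class = "evolution_call"))
  # parent within the restricted tree = nearest surviving ancestor (0 = root)
  rparent <- vapply(events, function(j) {
    v <- tree$parent[j]
    while (v != 0L && !surviving[v]) v <- tree$parent[v]
    v
  }, 0L)
  children <- lapply(c(0L, events), function(v) events[rparent == v])
  names(children) <- c("root", tree$labels[events])
  n_children <- lengths(children)
  is_leaf <- stats::setNames(n_children[-1L] == 0L, tree$labels[events])
  branch_nodes <- names(children)[n_children >= 2L]
  linear <- length(branch_nodes) == 0L ||
    (terminal_fork_linear && length(branch_nodes) == 1L &&
       all(is_leaf[tree$labels[children[[branch_nodes]]]]))
  pattern <- if (linear) "linear" else "branching"

  if (is.null(genes)) {
    genes <- stats::setNames(sub("_[^_]*$", "", tree$labels), tree$labels)
  }
  unit <- genes[tree$labels[events]]
  if (!is.null(pathway_map)) {
    mapped <- pathway_map[unit]
    unit <- ifelse(is.na(mapped), unit, mapped)
  }
  convergent_events <- list()
  if (pattern == "branching") {
    for (g in unique(unit[duplicated(unit)])) {
      evs <- events[unit == g]
      for (a in seq_along(evs)) for (b in seq_along(evs)) {
        if (a < b && !is_ancestor(tree, evs[a], evs[b]) &&
            !is_ancestor(tree, evs[b], evs[a])) {
          convergent_events[[length(convergent_events) + 1L]] <-
            tree$labels[c(evs[a], evs[b])]
        }
      }
    }
  }
  structure(list(pattern = pattern,
                 convergent = length(convergent_events) > 0L,
                 branch_points = branch_nodes,
                 convergent_events = convergent_events),
            class = "evolution_call")
}

#' @export
print.evolution_call <- function(x, ...) {
  cat("evolution pattern:", x$pattern,
      if (x$convergent) "(convergent)" else "", "\n")
  invisible(x)
}

#' Default gene-to-pathway map for AML driver panels
#'
#' Standard functional groupings of recurrently mutated AML genes:
#' nucleophosmin, DNA methylation, RTK/RAS/MAPK signaling, JAK-STAT,
#' transcription factors, chromatin/cohesin, splicing, and apoptosis.
#'
#' @return Named character vector gene -> pathway.
#' @export
default_pathway_map <- function() {
  c(NPM1 = "nucleophosmin",
    DNMT3A = "DNA_methylation", TET2 = "DNA_methylation",
    IDH1 = "DNA_methylation", IDH2 = "DNA_methylation",
    FLT3 = "RTK_RAS_MAPK", NRAS = "RTK_RAS_MAPK", KRAS = "RTK_RAS_MAPK",
    PTPN11 = "RTK_RAS_MAPK", KIT = "RTK_RAS_MAPK", CBL = "RTK_RAS_MAPK",
    NF1 = "RTK_RAS_MAPK", BRAF = "RTK_RAS_MAPK",
    JAK2 = "JAK_STAT", MPL = "JAK_STAT", CSF3R = "JAK_STAT",
    RUNX1 = "transcription_factor", CEBPA = "transcription_factor",
    GATA2 = "transcription_factor", ETV6 = "transcription_factor",
    WT1 = "transcription_factor",
    ASXL1 = "chromatin_cohesin", EZH2 = "chromatin_cohesin",
    STAG2 = "chromatin_cohesin", BCOR = "chromatin_cohesin",
    RAD21 = "chromatin_cohesin", SMC1A = "chromatin_cohesin",
    SMC3 = "chromatin_cohesin", KMT2A = "chromatin_cohesin",
    SRSF2 = "splicing", SF3B1 = "splicing", U2AF1 = "splicing",
    ZRSR2 = "splicing",
    TP53 = "apoptosis", PPM1D = "apoptosis")
}

#' Write a clonal composition and fishplot-ready prevalence matrix
#'
#' @param composition A `clonal_composition`.
#' @param path Composition TSV path.
#' @param prevalence_path Optional path for the timepoints x clones
#'   prevalence matrix TSV.
#' @export
write_composition_tsv <- function(composition, path, prevalence_path = NULL) {
  rows <- do.call(rbind, lapply(names(composition$subclones), function(t) {
    df <- composition$subclones[[t]]
    if (nrow(df) == 0L) return(NULL)
    cbind(timepoint = t, df)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(prevalence_path)) {
    clones <- unique(unlist(lapply(composition$subclones, `[[`, "clone")))
    prev <- t(vapply(composition$subclones, function(df) {
      x <- stats::setNames(rep(0, length(clones)), clones)
      x[df$clone] <- df$fraction
      x
    }, numeric(length(clones))))
    utils::write.table(data.frame(timepoint = rownames(prev), prev,
                                  check.names = FALSE),
                       prevalence_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
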