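#' Construct a mutation tree
#'
#' A mutation tree is a rooted tree whose non-root nodes are mutation (or
#' loss-of-heterozygosity) acquisition events. The root represents the
#' wild-type state. A cell attached at a node carries every event on the
#' path from the root to that node.
#'
#' @param parent Integer vector of length `n_events`; `parent[j]` is the
#'   parent of event `j`, with `0` denoting the root. Events are indexed
#'   `1..n_events` in the order of `labels`.
#' @param labels Character vector of event names (default `"m1".."mJ"`).
#' @return An object of class `mutation_tree` with fields `parent` and
#'   `labels`.
#' @export
mutation_tree <- function(parent, labels = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L) stop("a mutation tree needs at least one event")
  if (is.null(labels)) labels <- paste0("m", seq_len(n))
  if (length(labels) != n) stop("labels must match the number of events")
  if (any(parent < 0L | parent > n)) stop("parent indices out of range")
  tr <- structure(list(parent = parent, labels = as.character(labels)),
                  class = "mutation_tree")
  validate_tree(tr)
  tr
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat("mutation tree with", length(x$parent), "events\n")
  cat(tree_to_newick(x), "\n")
  invisible(x)
}

validate_tree <- function(tree) {
  parent <- tree$parent
  n <- length(parent)
  # every node must reach the root without cycles
  for (j in seq_len(n)) {
    v <- j
    steps <- 0L
    while (v != 0L) {
      v <- parent[v]
      steps <- steps + 1L
      if (steps > n) stop("parent map contains a cycle")
    }
  }
  invisible(tree)
}

#' Ancestor indicator matrix of a mutation tree
#'
#' @param tree A `mutation_tree`.
#' @return Logical matrix `(n_events + 1) x n_events`; row `v` (node `v - 1`,
#'   where node 0 is the root) indicates which events lie on the path from
#'   the root to that node (ancestor-or-self).
#' @export
ancestor_matrix <- function(tree) {
  n <- length(tree$parent)
  A <- matrix(FALSE, n + 1L, n, dimnames = list(NULL, tree$labels))
  for (v in seq_len(n)) {
    u <- v
    while (u != 0L) {
      A[v + 1L, u] <- TRUE
      u <- tree$parent[u]
    }
  }
  A
}

#' Test ancestry between two events
#'
#' @param tree A `mutation_tree`.
#' @param anc,node Event indices.
#' @param proper If `TRUE` (default) `anc == node` returns `FALSE`.
#' @return Logical.
#' @export
is_ancestor <- function(tree, anc, node, proper = TRUE) {
  if (anc == node) return(!proper)
  v <- node
  while (v != 0L) {
    v <- tree$parent[v]
    if (v == anc) return(TRUE)
  }
  FALSE
}

tree_children <- function(tree) {
  n <- length(tree$parent)
  lapply(0:n, function(v) which(tree$parent == v))
}

#' Serialize a mutation tree to Newick
#'
#' Mutation trees routinely contain chains of single-child internal nodes
#' (one event following another with no branching), which the standard
#' `phylo` representation collapses; the exporter therefore writes the
#' string directly. Every node carries its event label; the root is
#' labelled `root`.
#'
#' @param tree A `mutation_tree`.
#' @return A Newick string.
#' @export
tree_to_newick <- function(tree) {
  ch <- tree_children(tree)
  rec <- function(v) {
    lab <- if (v == 0L) "root" else tree$labels[v]
    kids <- ch[[v + 1L]]
    if (length(kids) == 0L) return(lab)
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")", lab)
  }
  paste0(rec(0L), ";")
}

#' Serialize a mutation tree to a JSON parent map
#'
#' @param tree A `mutation_tree`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(labels = tree$labels, parent = tree$parent)
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse a mutation tree from a JSON parent map
#'
#' @param path File written by [tree_to_json()].
#' @return A `mutation_tree`.
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mutation_tree(obj$parent, obj$labels)
}
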