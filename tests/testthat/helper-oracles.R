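# Independent oracles used to cross-check the implementation. These are
# deliberately written from the model definitions, not by calling package
# internals.

# direct genotype-filter decision rule: missing below 10x; mutant needs
# alt >= 3 and the depth-band VAF cut (15% for 20-99x, 10% for >= 100x,
# no VAF clause at 10-19x)
oracle_call_genotype <- function(depth, alt) {
  if (depth < 10) return(3L)
  if (alt < 3) return(0L)
  vaf <- alt / depth
  if (depth >= 100) return(if (vaf >= 0.10) 1L else 0L)
  if (depth >= 20) return(if (vaf >= 0.15) 1L else 0L)
  1L
}

# marginalized tree likelihood computed by direct matrix algebra
oracle_loglik <- function(G, parent, alpha, beta) {
  n_loci <- ncol(G)
  beta <- rep_len(beta, n_loci)
  A <- matrix(0, n_loci + 1L, n_loci)  # node (root first) x event
  for (v in seq_len(n_loci)) {
    u <- v
    while (u != 0L) {
      A[v + 1L, u] <- 1
      u <- parent[u]
    }
  }
  L0 <- matrix(0, nrow(G), n_loci)  # log P(D | event absent)
  L1 <- matrix(0, nrow(G), n_loci)  # log P(D | event present)
  for (j in seq_len(n_loci)) {
    d <- G[, j]
    L0[, j] <- ifelse(d == 0, log(1 - alpha), ifelse(d == 1, log(alpha), 0))
    L1[, j] <- ifelse(d == 0, log(beta[j]),
                      ifelse(d == 1, log(1 - beta[j]), 0))
  }
  S <- L0 %*% t(1 - A) + L1 %*% t(A)  # cells x nodes
  mx <- apply(S, 1L, max)
  sum(mx + log(rowMeans(exp(S - mx))))
}

# all valid parent vectors (rooted forests attached to node 0) on J events
enumerate_parent_vectors <- function(J) {
  grid <- as.matrix(expand.grid(rep(list(0:J), J)))
  ok <- apply(grid, 1L, function(parent) {
    if (any(parent == seq_len(J))) return(FALSE)
    for (j in seq_len(J)) {
      v <- j
      for (s in seq_len(J + 1L)) {
        if (v == 0L) break
        v <- parent[v]
      }
      if (v != 0L) return(FALSE)
    }
    TRUE
  })
  grid[ok, , drop = FALSE]
}

# Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

oracle_haldane_log2_or <- function(a, b, c, d) {
  log2(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# checks that every pair of mutated-cell sets is nested or disjoint
is_perfect_phylogeny <- function(G) {
  J <- ncol(G)
  for (i in seq_len(J - 1L)) for (j in (i + 1L):J) {
    ci <- G[, i] >= 1L
    cj <- G[, j] >= 1L
    both <- sum(ci & cj)
    if (both > 0L && both < min(sum(ci), sum(cj))) return(FALSE)
  }
  TRUE
}
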