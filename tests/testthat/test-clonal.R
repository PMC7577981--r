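fit_composition <- function(tr, fractions, n_cells, seed = 1,
                            threshold = 0.01) {
  gt <- genotypes_from_tree(tr, fractions, n_cells, seed = seed)
  fit <- mcmc_infer(gt$genotypes, error_model(fpr = 1e-6, fnr = 1e-6),
                    mcmc_config(chain_length = 3000, n_chains = 1,
                                seed = seed, model_id = 2))
  compose_clones(attach_cells(fit), threshold = threshold)
}

test_that("clonal composition counts cells and excludes wild type", {
  # linear tree A -> B with 60 cells at A and 40 at B
  tr <- mutation_tree(c(0L, 1L), labels = c("A", "B"))
  gt <- list(genotypes = rbind(matrix(rep(c(1L, 0L), 60), ncol = 2, byrow = TRUE),
                               matrix(1L, 40, 2)))
  colnames(gt$genotypes) <- c("A", "B")
  fit <- mcmc_infer(gt$genotypes, error_model(fpr = 1e-6, fnr = 1e-6),
                    mcmc_config(chain_length = 3000, n_chains = 1, seed = 1,
                                model_id = 2))
  comp <- compose_clones(attach_cells(fit))
  df <- comp$subclones[[1L]]
  expect_equal(df$clone, c("A", "B"))
  expect_equal(df$mutations, c("A", "A,B"))
  expect_equal(df$n_cells, c(60, 40))
  expect_equal(df$fraction, c(0.6, 0.4))
  expect_equal(unname(comp$wt_cell_count[1L]), 0L)
})

test_that("all cells at the root give an empty subclone list", {
  tr <- mutation_tree(c(0L, 1L), labels = c("A", "B"))
  G <- matrix(0L, 50, 2, dimnames = list(NULL, c("A", "B")))
  fit <- mcmc_infer(G, error_model(fpr = 1e-6, fnr = 1e-6),
                    mcmc_config(chain_length = 1000, n_chains = 1, seed = 1,
                                model_id = 2))
  comp <- compose_clones(attach_cells(fit))
  expect_equal(nrow(comp$subclones[[1L]]), 0L)
  expect_equal(unname(comp$wt_cell_count[1L]), 50L)
})

test_that("composition conserves cells and normalizes fractions", {
  for (s in 1:3) {
    tr <- simulate_tree(5, seed = s)
    f <- simulate_clone_fractions(tr, 2, 0.15, seed = s)
    comp <- fit_composition(tr, f[, 1L], 800, seed = s)
    df <- comp$subclones[[1L]]
    expect_equal(sum(df$n_cells) + unname(comp$wt_cell_count[1L]), 800)
    if (nrow(df) > 0L)
      expect_equal(sum(df$fraction), 1, tolerance = 1e-9)
  }
})

test_that("a rich convergent structure is recovered clone by clone", {
  # 12 mutated clones in a two-branch convergent topology
  parent <- c(0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 4L)
  labels <- c("NPM1", "IDH1", "IDH2", "FLT3_a", "KRAS_a", "PTPN11_a",
              "FLT3_b", "KRAS_b", "NRAS_a", "NRAS_b", "PTPN11_b", "WT1")
  tr <- mutation_tree(parent, labels)
  fr <- c(0.04, rep(0.96 / 12, 12))
  comp <- fit_composition(tr, fr, 4800, seed = 9)
  df <- comp$subclones[[1L]]
  expect_equal(nrow(df), 12L)
  expect_true(all(!df$below_threshold))
  call <- classify_evolution(tr, comp)
  expect_equal(call$pattern, "branching")
  expect_true(call$convergent)
})

test_that("shannon_index matches closed forms and vegan", {
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(shannon_index(rep(25, 4)), 2)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5)
  # maximal iff equal, zero iff single clone
  expect_lt(shannon_index(c(0.7, 0.1, 0.1, 0.1)), 2)
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    set.seed(s)
    x <- rgamma(6, 2)
    expect_equal(shannon_index(x),
                 unname(vegan::diversity(x, index = "shannon", base = 2)),
                 tolerance = 1e-12)
  }
})

test_that("shannon_index works on compositions and rejects empty ones", {
  tr <- mutation_tree(c(0L, 1L, 1L, 3L))
  comp <- fit_composition(tr, c(0.2, 0.2, 0.2, 0.2, 0.2), 1000, seed = 3)
  h <- shannon_index(comp)
  expect_gt(h, 1.9)
  expect_lte(h, 2 + 1e-9)
  empty <- comp
  empty$subclones[[1L]] <- empty$subclones[[1L]][0L, ]
  expect_error(shannon_index(empty), "empty")
})

test_that("evolution patterns follow the branch-point rule", {
  # pure path: linear
  expect_equal(classify_evolution(mutation_tree(c(0L, 1L, 2L)))$pattern,
               "linear")
  # terminal fork: linear by default, branching under the strict rule
  fork <- mutation_tree(c(0L, 1L, 1L))
  expect_equal(classify_evolution(fork)$pattern, "linear")
  expect_equal(classify_evolution(fork,
                                  terminal_fork_linear = FALSE)$pattern,
               "branching")
  # non-terminal fork: branching
  tr <- mutation_tree(c(0L, 1L, 1L, 2L))
  expect_equal(classify_evolution(tr)$pattern, "branching")
  # two separate branch points: branching even though each fork is terminal
  tr2 <- mutation_tree(c(0L, 1L, 1L, 0L, 4L, 4L))
  expect_equal(classify_evolution(tr2)$pattern, "branching")
})

test_that("convergent evolution needs parallel hits on disjoint branches", {
  labels <- c("NPM1", "IDH1", "IDH2", "FLT3_a", "FLT3_b")
  tr <- mutation_tree(c(0L, 1L, 1L, 2L, 3L), labels)
  call <- classify_evolution(tr)
  expect_equal(call$pattern, "branching")
  expect_true(call$convergent)  # FLT3_a and FLT3_b on disjoint branches
  expect_true(any(vapply(call$convergent_events, function(x)
    setequal(x, c("FLT3_a", "FLT3_b")), TRUE)))
  # same-gene hits on the SAME lineage are not convergent
  tr2 <- mutation_tree(c(0L, 1L, 1L, 2L, 4L), labels)
  expect_false(classify_evolution(tr2)$convergent)
  # pathway-level convergence via the shipped AML map
  labels3 <- c("NPM1", "IDH1", "IDH2", "KRAS", "NRAS")
  tr3 <- mutation_tree(c(0L, 1L, 1L, 2L, 3L), labels3)
  call3 <- classify_evolution(tr3, pathway_map = default_pathway_map())
  expect_true(call3$convergent)  # IDH1/IDH2 and KRAS/NRAS parallel branches
})

test_that("classification is topology-only above the survival threshold", {
  tr <- mutation_tree(c(0L, 1L, 1L, 2L))
  # kill the subclones that make the tree branch: only the chain survives
  comp <- fit_composition(tr, c(0.05, 0.45, 0.44, 0.01, 0.05), 2000, seed = 5,
                          threshold = 0.05)
  call <- classify_evolution(tr, comp)
  expect_equal(call$pattern, "linear")
})

test_that("branching trees are more diverse than chains of equal size", {
  # under depth-decaying clone sizes, chains concentrate mass in early
  # clones while bushy trees keep clones at comparable depths
  h_linear <- sapply(1:60, function(s) {
    chain <- mutation_tree(0:5)
    f <- simulate_clone_fractions(chain, 5, 0.1, depth_decay = 0.5, seed = s)
    shannon_index(f[-1L, 1L])
  })
  h_branch <- sapply(1:60, function(s) {
    bush <- mutation_tree(c(0L, 1L, 1L, 2L, 2L, 3L))
    f <- simulate_clone_fractions(bush, 5, 0.1, depth_decay = 0.5,
                                  seed = 1000 + s)
    shannon_index(f[-1L, 1L])
  })
  expect_gt(mean(h_branch), mean(h_linear))
})

test_that("composition and prevalence matrices serialize to TSV", {
  tr <- mutation_tree(c(0L, 1L))
  comp <- fit_composition(tr, c(0.2, 0.5, 0.3), 500, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_composition_tsv(comp, p1, p2)
  df <- read.delim(p1)
  expect_equal(nrow(df), 2L)
  prev <- read.delim(p2, check.names = FALSE)
  expect_equal(unname(unlist(prev[1L, -1L])), df$fraction, tolerance = 1e-9)
})
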