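test_that("simulate_tree is a random recursive tree with the right law", {
  expect_error(simulate_tree(0, seed = 1), "positive")
  # a single mutation has only one topology
  expect_equal(simulate_tree(1, seed = 99)$parent, 0L)
  # determinism
  expect_identical(simulate_tree(6, seed = 7)$parent,
                   simulate_tree(6, seed = 7)$parent)
  # two events: fork w.p. 1/2, each chain w.p. 1/4 (second event picks its
  # parent uniformly from {root, m1})
  shapes <- vapply(1:10000, function(s) {
    p <- simulate_tree(2, seed = s)$parent
    if (all(p == 0L)) "fork" else if (p[2L] == 1L) "chain12" else "chain21"
  }, "")
  n <- length(shapes)
  se_half <- sqrt(0.5 * 0.5 / n)
  se_quarter <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(shapes == "fork") - 0.5), 3 * se_half)
  expect_lt(abs(mean(shapes == "chain12") - 0.25), 3 * se_quarter)
  expect_lt(abs(mean(shapes == "chain21") - 0.25), 3 * se_quarter)
})

test_that("clone fractions normalize, respect drift and symmetry limits", {
  tr <- simulate_tree(4, seed = 2)
  f <- simulate_clone_fractions(tr, 1, wt_fraction = 0.2, n_timepoints = 3,
                                drift = 0, seed = 5)
  expect_equal(colSums(f), c(t1 = 1, t2 = 1, t3 = 1), tolerance = 1e-9)
  expect_equal(f[, 1L], f[, 2L])
  expect_equal(f[, 1L], f[, 3L])
  # alpha -> Inf limit: equal mutated fractions
  f2 <- simulate_clone_fractions(tr, 1e7, wt_fraction = 0.2, seed = 5)
  expect_equal(unname(f2[-1L, 1L]), rep(0.2, 4), tolerance = 1e-3)
  # drifted timepoints still normalize
  f3 <- simulate_clone_fractions(tr, 1, wt_fraction = 0.1, n_timepoints = 4,
                                 drift = 0.5, seed = 6)
  expect_equal(unname(colSums(f3)), rep(1, 4), tolerance = 1e-9)
  expect_false(identical(f3[, 1L], f3[, 2L]))
  expect_error(simulate_clone_fractions(tr, 1, wt_fraction = 1), "wt_fraction")
})

test_that("true genotypes follow tree ancestry, including LOH", {
  # linear tree root -> A -> B
  tr <- mutation_tree(c(0L, 1L), labels = c("A", "B"))
  gt <- genotypes_from_tree(tr, c(0, 0, 1), 50, seed = 1)  # all cells at B
  expect_true(all(gt$genotypes == 1L))
  gt0 <- genotypes_from_tree(tr, c(1, 0, 0), 50, seed = 1)  # all at root
  expect_true(all(gt0$genotypes == 0L))
  # root -> A(het) -> A_loh: cells at the LOH node are homozygous for A
  tr2 <- mutation_tree(c(0L, 1L), labels = c("A", "A_loh"))
  gt2 <- genotypes_from_tree(tr2, c(0, 0, 1), 20,
                             loh_events = list(list(locus = 1L, node = 2L)),
                             seed = 3)
  expect_true(all(gt2$genotypes[, "A"] == 2L))
  # LOH node must descend from the het event
  expect_error(
    genotypes_from_tree(mutation_tree(c(0L, 0L)), c(1, 0, 0) , 5,
                        loh_events = list(list(locus = 1L, node = 2L))),
    "descendant")
})

test_that("noiseless generated matrices satisfy perfect phylogeny", {
  for (s in 1:5) {
    tr <- simulate_tree(6, seed = s)
    f <- simulate_clone_fractions(tr, 1, 0.1, seed = s)
    gt <- genotypes_from_tree(tr, f[, 1L], 300, seed = s)
    expect_true(is_perfect_phylogeny(gt$genotypes))
  }
})

test_that("observation noise matches its nominal rates", {
  G <- matrix(0L, 500, 100)
  expect_identical(add_observation_noise(G, 0, 0, 0, 0, seed = 1), G)
  # fnr = 1 wipes out all true mutants
  G1 <- matrix(1L, 100, 10)
  expect_true(all(add_observation_noise(G1, 0, 1, 0, 0, seed = 1) == 0L))
  # binomial check on the false-positive rate over 50,000 true-0 entries
  obs <- add_observation_noise(G, fpr = 0.01, fnr = 0, seed = 2)
  frac1 <- mean(obs == 1L)
  expect_lt(abs(frac1 - 0.01), 3 * sqrt(0.01 * 0.99 / 50000))
  # per-locus missing rate converges
  obs2 <- add_observation_noise(G, fpr = 0, fnr = 0,
                                missing_rate = c(rep(0.2, 50), rep(0, 50)),
                                seed = 3)
  miss <- colMeans(obs2 == 3L)
  expect_lt(max(abs(miss[1:50] - 0.2)), 3 * sqrt(0.2 * 0.8 / 500) + 0.02)
  expect_true(all(miss[51:100] == 0))
  expect_error(add_observation_noise(G, fpr = 2), "rates")
  # determinism
  expect_identical(add_observation_noise(G1, .05, .1, .1, .05, seed = 9),
                   add_observation_noise(G1, .05, .1, .1, .05, seed = 9))
})

test_that("doublets take the elementwise maximum of two true rows", {
  G <- rbind(c(1L, 0L), c(0L, 1L))
  set.seed(NULL)
  obs <- add_observation_noise(G[rep(1:2, 50), ], fpr = 0, fnr = 0,
                               doublet_rate = 1, seed = 4)
  # with doublet_rate 1 every cell merges with a random partner; merged rows
  # are the max of two true rows, so only patterns 10, 01, 11 can occur and
  # 11 must appear
  pat <- apply(obs, 1L, paste, collapse = "")
  expect_true(all(pat %in% c("10", "01", "11")))
  expect_true(any(pat == "11"))
})

test_that("read-count simulation respects genotype expectations", {
  # wild type with no base error yields zero alternate reads
  G0 <- matrix(0L, 200, 5)
  rc <- simulate_read_counts(G0, mean_depth = 50, ado = 0, base_error = 0,
                             seed = 1)
  expect_true(all(rc$alt == 0L))
  expect_true(all(rc$alt <= rc$depth))
  # het with no dropout: pooled alt fraction ~ 0.5
  G1 <- matrix(1L, 2000, 2)
  rc1 <- simulate_read_counts(G1, mean_depth = 100, ado = 0,
                              base_error = 0, seed = 2)
  vaf <- sum(rc1$alt) / sum(rc1$depth)
  expect_lt(abs(vaf - 0.5), 0.01)
  # determinism
  rc2 <- simulate_read_counts(G1, mean_depth = 100, ado = 0,
                              base_error = 0, seed = 2)
  expect_identical(rc1, rc2)
  expect_error(simulate_read_counts(G1, mean_depth = 0), "positive")
})

test_that("simulated samples are reproducible end to end under a seed", {
  s1 <- simulate_sample(n_mutations = 4, n_cells = 200, n_snps = 3, seed = 11)
  s2 <- simulate_sample(n_mutations = 4, n_cells = 200, n_snps = 3, seed = 11)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$tree$parent, s2$truth$tree$parent)
  # truth serializes to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_truth(s1$truth, path)
  truth <- jsonlite::fromJSON(path)
  expect_equal(truth$parent, s1$truth$tree$parent)
})

test_that("depth decay makes deeper clones smaller in expectation", {
  chain <- mutation_tree(c(0L, 1L, 2L, 3L))
  f <- sapply(1:200, function(s)
    simulate_clone_fractions(chain, 5, 0.1, depth_decay = 0.5,
                             seed = s)[, 1L])
  means <- rowMeans(f)[-1L]
  expect_true(all(diff(means) < 0))
})
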