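test_that("tree likelihood matches hand arithmetic and the matrix oracle", {
  # one cell, one locus, observed mutant: 1/2 * alpha + 1/2 * (1 - beta)
  ll <- tree_log_likelihood(matrix(1L, 1, 1), mutation_tree(0L),
                            error_model(fpr = 0.01, fnr = 0.2))
  expect_equal(ll, log(0.5 * 0.01 + 0.5 * 0.8), tolerance = 1e-12)
  expect_equal(round(ll, 4), -0.9039)
  # random instances against an independently coded likelihood
  for (s in 1:20) {
    set.seed(s)
    J <- sample(2:6, 1L)
    tr <- simulate_tree(J, seed = s)
    G <- matrix(sample(c(0L, 1L, 3L), 15L * J, TRUE, prob = c(.5, .4, .1)),
                15L, J)
    err <- error_model(fpr = 0.01, fnr = runif(1L, 0.02, 0.3))
    expect_equal(tree_log_likelihood(G, tr, err),
                 oracle_loglik(G, tr$parent, err$fpr, err$fnr),
                 tolerance = 1e-9)
  }
})

test_that("noiseless data attains the -n*log(E+1) bound at the true tree", {
  tr <- mutation_tree(c(0L, 1L, 2L))
  f <- c(0.25, 0.25, 0.25, 0.25)
  gt <- genotypes_from_tree(tr, f, 120, seed = 1)
  err <- error_model(fpr = 1e-12, fnr = 1e-12)
  ll <- tree_log_likelihood(gt$genotypes, tr, err)
  expect_equal(ll, -120 * log(4), tolerance = 1e-6)
})

test_that("likelihood is invariant to permuting cell rows", {
  set.seed(42)
  tr <- simulate_tree(5, seed = 3)
  G <- matrix(sample(c(0L, 1L, 3L), 200, TRUE), 40, 5)
  err <- error_model(fpr = 0.01, fnr = 0.1)
  expect_equal(tree_log_likelihood(G, tr, err),
               tree_log_likelihood(G[sample(40), ], tr, err))
})

test_that("binary view is enforced and trees must cover all loci", {
  err <- error_model()
  expect_error(tree_log_likelihood(matrix(2L, 1, 1), mutation_tree(0L), err),
               "binary view")
  expect_error(tree_log_likelihood(matrix(1L, 1, 2), mutation_tree(0L), err),
               "cover")
})

test_that("MCMC recovers small trees and is deterministic under a seed", {
  tr <- mutation_tree(c(0L, 1L, 1L, 3L))
  gt <- genotypes_from_tree(tr, rep(0.2, 5), 400, seed = 8)
  obs <- add_observation_noise(gt$genotypes, 0.01, 0.08, seed = 9)
  err <- error_model(fpr = 0.01, fnr = 0.08)
  cfg <- mcmc_config(chain_length = 5000, n_chains = 2, seed = 4,
                     model_id = 2)
  fit <- mcmc_infer(obs, err, cfg)
  expect_equal(fit$map_tree$parent, tr$parent)
  fit2 <- mcmc_infer(obs, err, cfg)
  expect_identical(fit$parents, fit2$parents)
  expect_identical(fit$map_loglik, fit2$map_loglik)
  expect_true(fit$rhat < 1.1)
})

test_that("model 3 reduces to model 1 on complete data", {
  tr <- mutation_tree(c(0L, 1L))
  gt <- genotypes_from_tree(tr, c(0.3, 0.4, 0.3), 150, seed = 2)
  obs <- add_observation_noise(gt$genotypes, 0.01, 0.06, seed = 3)
  err <- error_model(fpr = 0.01, fnr = 0.06)
  f1 <- mcmc_infer(obs, err, mcmc_config(chain_length = 4000, n_chains = 1,
                                         seed = 5, model_id = 1))
  f3 <- mcmc_infer(obs, err, mcmc_config(chain_length = 4000, n_chains = 1,
                                         seed = 5, model_id = 3))
  expect_identical(f1$parents, f3$parents)
  expect_identical(f1$beta, f3$beta)
})

test_that("degenerate inputs are handled explicitly", {
  err <- error_model()
  expect_error(mcmc_infer(matrix(integer(0), 0, 2), err), "empty")
  G <- cbind(m1 = c(1L, 0L, 1L), m2 = c(3L, 3L, 3L))
  expect_warning(fit <- mcmc_infer(G, err, mcmc_config(chain_length = 500,
                                                       n_chains = 1, seed = 1,
                                                       model_id = 2)),
                 "all-missing")
  expect_equal(length(fit$map_tree$parent), 1L)
  expect_error(mcmc_config(model_id = 5), "model_id")
  expect_error(mcmc_config(burn_in = 1), "burn_in")
  G4 <- cbind(c(3L, 3L), c(1L, 3L))
  expect_error(mcmc_infer(G4, err, mcmc_config(chain_length = 500,
                                               n_chains = 1, model_id = 3)),
               "complete")
})

test_that("label-permutation equivariance of the MAP tree", {
  tr <- mutation_tree(c(0L, 1L, 2L, 1L))
  gt <- genotypes_from_tree(tr, rep(0.2, 5), 500, seed = 13)
  obs <- add_observation_noise(gt$genotypes, 0.01, 0.05, seed = 14)
  colnames(obs) <- paste0("m", 1:4)
  err <- error_model(fpr = 0.01, fnr = 0.05)
  cfg <- mcmc_config(chain_length = 6000, n_chains = 1, seed = 6,
                     model_id = 2)
  fit <- mcmc_infer(obs, err, cfg)
  perm <- c(3L, 1L, 4L, 2L)  # new order of loci
  fitp <- mcmc_infer(obs[, perm], err, cfg)
  # relabel fitp's parents back into the original locus indexing
  back <- match(seq_len(4L), perm)
  relabel <- function(p) ifelse(p == 0L, 0L, perm[pmax(p, 1L)])
  expect_equal(relabel(fitp$map_tree$parent)[back], fit$map_tree$parent)
})

test_that("zygosity encoding splits LOH loci and orders the events", {
  G <- cbind(RUNX1 = c(0L, 1L, 2L, 3L), FLT3 = c(1L, 0L, 1L, 1L))
  enc <- encode_zygosity(G)
  expect_equal(colnames(enc$binary), c("RUNX1", "RUNX1_loh", "FLT3"))
  # het cell: mutation row 1, LOH row 0; hom cell: both rows 1
  expect_equal(unname(enc$binary[, "RUNX1"]), c(0L, 1L, 1L, 3L))
  expect_equal(unname(enc$binary[, "RUNX1_loh"]), c(0L, 0L, 1L, 3L))
  expect_equal(unname(enc$binary[, "FLT3"]), c(1L, 0L, 1L, 1L))
  expect_equal(enc$constraints, matrix(c(1L, 2L), 1L))
  # loci without hom calls stay single events
  enc2 <- encode_zygosity(cbind(a = c(0L, 1L)))
  expect_equal(ncol(enc2$binary), 1L)
  expect_equal(nrow(enc2$constraints), 0L)
  expect_error(encode_zygosity(cbind(a = 4L)), "codes")
})

test_that("constrained search never violates het-before-hom ordering", {
  # truth: root -> M -> L (RUNX1 het then LOH), plus an independent event
  tr <- mutation_tree(c(0L, 1L), labels = c("RUNX1", "RUNX1_loh"))
  gt <- genotypes_from_tree(mutation_tree(0L, "RUNX1"), c(0.3, 0.7), 300,
                            loh_events = list(), seed = 1)
  G <- gt$genotypes
  # make a third of the mutant cells homozygous (LOH subclone)
  mut <- which(G[, 1L] == 1L)
  G[mut[seq_len(floor(length(mut) / 3))], 1L] <- 2L
  obs <- add_observation_noise(G, 0.01, 0.06, seed = 2)
  enc <- encode_zygosity(obs)
  fit <- mcmc_infer(enc$binary, error_model(fpr = 0.01, fnr = 0.06),
                    mcmc_config(chain_length = 4000, n_chains = 1, seed = 3,
                                model_id = 2),
                    constraints = enc$constraints)
  ok <- apply(fit$parents, 1L, function(p) {
    tree <- mutation_tree(p)
    all(apply(enc$constraints, 1L, function(cn)
      is_ancestor(tree, cn[1L], cn[2L])))
  })
  expect_true(all(ok))
  expect_true(is_ancestor(fit$map_tree, 1L, 2L))
})

test_that("consensus report compares all four model configurations", {
  tr <- mutation_tree(c(0L, 1L))
  gt <- genotypes_from_tree(tr, c(0.2, 0.4, 0.4), 200, seed = 7)
  err <- error_model(fpr = 0.01, fnr = 0.05)
  cfg <- mcmc_config(chain_length = 3000, n_chains = 1, seed = 2)
  rep <- consensus_across_models(gt$genotypes, err, cfg)
  expect_equal(nrow(rep$pairwise), 6L)  # C(4,2)
  expect_true(rep$consistent)           # noiseless complete data
  expect_true(all(rep$map_parents[1L, ] == tr$parent))
})
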