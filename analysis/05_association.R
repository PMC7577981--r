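#!/usr/bin/env Rscript
# Stage 5: mutation co-occurrence and mutual exclusivity. Within the demo
# sample, all locus pairs are tested at the cell level (Haldane-corrected
# log2 odds ratio, Fisher exact test, BH adjustment). A small simulated
# cohort then illustrates the two cohort-level analyses: per-patient bulk
# presence/absence (natural-log OR + G-test) and pooled clone-level tables.

library(clonalevo)

cfg <- list(out_dir = "scratch/run", seed = 1L, stages = "cooccur")
run_pipeline(cfg)

dir.create("results", showWarnings = FALSE)
invisible(file.copy(file.path(cfg$out_dir, "cooccurrence.tsv"),
                    "results/cell_cooccurrence.tsv", overwrite = TRUE))
cells <- read.delim(file.path(cfg$out_dir, "cooccurrence.tsv"))
cat("cell-level pairs tested:", nrow(cells), "\n")
sig <- cells[!is.na(cells$q) & cells$q < 0.05, ]
cat("significant at q < 0.05:", nrow(sig), "\n")
print(head(sig[order(sig$q), c("pair_a", "pair_b", "log_or", "q")], 10))

# cohort-level demo: 25 simulated patients, each a small random tree over a
# shared gene panel; nested mutations co-occur, parallel ones exclude
set.seed(2)
genes <- c("NPM1", "DNMT3A", "FLT3", "NRAS", "IDH1", "TET2")
compositions <- list()
presence <- matrix(FALSE, 25, length(genes), dimnames = list(NULL, genes))
for (i in 1:25) {
  k <- sample(2:4, 1)
  muts <- sample(genes, k)
  tr <- simulate_tree(k, seed = i, labels = muts)
  f <- simulate_clone_fractions(tr, 2, 0.1, seed = i)
  gt <- genotypes_from_tree(tr, f[, 1], 1500, seed = i + 100)
  fit <- mcmc_infer(gt$genotypes,
                    error_model(fpr = 0.01, fnr = 0.058),
                    mcmc_config(chain_length = 4000, n_chains = 1,
                                seed = i, model_id = 2))
  comp <- compose_clones(attach_cells(fit, seed = i))
  compositions[[i]] <- comp
  presence[i, muts] <- TRUE
}
bulk <- bulk_cooccurrence(presence)
clones <- clone_cooccurrence(compositions, min_fraction = 0.01)
dir.create("results", showWarnings = FALSE)
write_cooccurrence_tsv(bulk, "results/bulk_cooccurrence.tsv")
write_cooccurrence_tsv(clones, "results/clone_cooccurrence.tsv",
                       "results/clone_logor_matrix.tsv")
cat("\ncohort-level (bulk presence/absence), top pairs by |log OR|:\n")
print(head(bulk[order(-abs(bulk$log_or)),
                c("pair_a", "pair_b", "log_or", "G", "p", "q")], 5))
cat("\nclone-level pooled analysis:", nrow(clones), "pairs written to",
    "results/clone_cooccurrence.tsv\n")
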