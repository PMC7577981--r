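#!/usr/bin/env Rscript
# Stage 1: generate the cohort-style synthetic sample that the rest of the
# analysis operates on: a random 8-event mutation tree, ~6,000 cells, a
# 10-SNP germline panel, allele dropout 5.8%, FPR 1%, mean amplicon depth
# 48x. Writes the ground truth, the observed genotype matrix, and the
# read-count matrices under scratch/run/.

library(clonalevo)

cfg <- list(out_dir = "scratch/run", seed = 1L, stages = "simulate",
            simulate = list(n_mutations = 8, n_cells = 6000, n_snps = 10,
                            ado = 0.058, fpr = 0.01, mean_depth = 48))
manifest <- run_pipeline(cfg)

truth <- jsonlite::fromJSON(file.path(cfg$out_dir, "truth.json"))
cat("simulated sample written to", cfg$out_dir, "\n")
cat("true tree:", tree_to_newick(mutation_tree(truth$parent, truth$labels)),
    "\n")
cat("clone fractions:",
    paste(round(truth$clone_fractions[, 1], 3), collapse = " "), "\n")
cat("stage runtime:", manifest$stages$simulate$runtime_s, "s\n")

dir.create("results", showWarnings = FALSE)
invisible(file.copy(file.path(cfg$out_dir, "truth.json"),
                    "results/truth.json", overwrite = TRUE))
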