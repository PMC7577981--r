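# clonalevo

Clonal evolution analysis of single-cell DNA sequencing (scDNA-seq) data,
for the setting typical of AML studies: targeted panels of a few dozen
driver loci genotyped in thousands of single cells per sample, with
allele dropout (ADO) around 5–7% and a ~1% false-positive rate.

The package takes per-cell read counts or genotype calls and reconstructs
how the tumor evolved:

1. **Genotype calling** — per cell-locus filter: missing below 10x depth;
   mutant requires alternate count ≥ 3 and single-cell VAF ≥ 15% (20–99x)
   or ≥ 10% (≥ 100x); ADO estimated from germline heterozygous SNP loci.
2. **Mutation-tree inference** — Bayesian MCMC over mutation trees under
   a false-positive/false-negative error model, marginalizing each cell's
   attachment:
   log L(T, β) = Σ_c log (E+1)⁻¹ Σ_v Π_j P(D_cj | E_j(v)),
   with P(1|0) = α (FPR), P(0|1) = β_j (FNR = ADO), missing entries
   contributing no factor. Four standard model configurations (all vs
   complete cells × learned vs fixed FNR), locus-specific FNR learning
   with a Gaussian prior (SD 0.002), zygosity-constrained search that
   orders heterozygous before homozygous (LOH) states, longitudinal
   attachment that forbids placing a cell below mutations unobserved at
   its sampling time, and 95% credible intervals on subclone sizes from
   posterior sampling. The sampler core is compiled (Rcpp) and collapses
   identical genotype patterns, so 10⁶ iterations on a 6,000-cell sample
   take seconds.
3. **Clonal analysis** — subclones (cell populations carrying ≥ 1
   mutation; wild-type excluded), clone fractions with credible
   intervals, Shannon diversity H = −Σ p_i log2 p_i, and
   linear/branching/convergent evolution-pattern classification.
4. **Co-occurrence statistics** — Haldane-corrected log odds ratios with
   Fisher exact tests (cell level, log2) or G-tests (patient and clone
   level, natural log), BH-adjusted.

A synthetic-data generator (`simulate_sample()` and friends) emulates the
whole data-generating process — random clonal trees, Dirichlet clone
fractions with optional timepoint drift, per-locus dropout/missingness,
doublets, negative-binomial read depths — so the entire pipeline is
testable end to end without any external data.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
cohort-style synthetic sample (8 driver mutations, 6,000 cells, 10 SNP
loci, ADO 5.8%, FPR 1%):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_genotype.R
Rscript analysis/03_infer.R
Rscript analysis/04_clonal.R
Rscript analysis/05_association.R
```

Output of the first four stages (abridged):

```
true tree: ((m1,(m3,m7)m2)m6,((m5)m4)m8)root;
estimated ADO from SNP panel: 5.9% (simulated at 5.8%)
MAP tree: ((m1,(m3,m7)m2)m6,((m5)m4)m8)root;
parent-vector agreement with the generating tree: 100%
four-model consistency: TRUE
subclones detected: 8
  clone mutations n_cells fraction ci_lower ci_upper
1    m1     m1,m6     312   0.0575   0.0551   0.0599
4    m4     m4,m8    1176   0.2253   0.2209   0.2296
8    m8        m8    1540   0.2943   0.2896   0.2988
evolution pattern: branching
Shannon index: 2.692 bits
```

Reading this: the MAP mutation tree reproduces the generating topology
exactly; the estimated allele dropout recovers the simulated 5.8%; each
subclone is reported with its mutation set (the events on its root path),
its hard-assigned cell count, and its fraction of mutated cells with a
95% credible interval; the tree has non-terminal forks, hence a branching
pattern, and the 8 clones of comparable size give a diversity of 2.69
bits (maximum for 8 clones would be 3). Stage 5 prints the cell-level
pairwise table — nested mutations come out co-occurring (log2 OR ≈ +4.5),
mutations on parallel branches mutually exclusive (log2 OR ≈ −5) — and a
small simulated cohort demonstrating the patient-level and clone-level
analyses.

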