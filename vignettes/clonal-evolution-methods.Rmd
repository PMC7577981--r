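---
title: "Inferring clonal evolution from single-cell DNA sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clonal evolution from single-cell DNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalevo)
```

`clonalevo` reconstructs the clonal evolution of a tumor from targeted
single-cell DNA sequencing (scDNA-seq) panels of the kind used in AML:
a few dozen driver loci genotyped in thousands of cells per sample. This
vignette is the package's account of the statistical machinery: the
genotype filter, the error model, the mutation-tree MCMC and its
extensions, the clonal summaries, and the co-occurrence statistics —
together with the judgement calls made where the design was genuinely
open, and what the synthetic-data tests do and do not establish.

## Genotype calling and quality model

Each cell-locus observation is a pair (depth `DP`, alternate count).
`call_genotype()` applies the standard amplicon filter: the call is
*missing* (code 3) below 10x; *mutant* (code 1) when the alternate count
is at least 3 and the single-cell VAF clears the depth band — 15% for
20–99x, 10% for 100x and above (both boundaries inclusive); otherwise
*wild type* (code 0). In the 10–19x band no VAF clause applies; this is
not an omission but an arithmetic fact, since `alt >= 3` at `DP <= 19`
already implies `VAF >= 3/19 > 0.15` (a property test pins this down).
Sub-band alternate evidence (`alt >= 3` but VAF below the band) is called
wild type by default on the rationale that the bands exist to suppress the
~1% per-call false-positive noise; `ambiguous_as_missing = TRUE` switches
to treating it as missing. An optional zygosity mode reports calls with
VAF at or above 0.9 as homozygous (code 2); homozygous calls on real
platforms are depth-sensitive, so this mode is a declared approximation.

**Allele dropout (ADO).** The dominant error in single-cell genotyping is
the failure to amplify one allele, turning heterozygous sites into
homozygous-looking ones. Panels include common germline SNP loci that are
known heterozygous in every cell; `estimate_ado()` is the fraction of
non-missing calls at those loci that look homozygous (reference *or*
alternate — both dropout directions count, which is why the estimator
wants zygosity-mode calls). Platforms do not publish their exact ADO
formula; ours is stated rather than claimed identical. Cohort-scale AML
data put the median ADO near 5.8%, which is the package-wide default.

## The mutation-tree model

The evolutionary history is encoded as a *mutation tree*: a rooted tree
whose non-root nodes are mutation-acquisition events; a cell attached at
node $v$ carries exactly the events on the root path of $v$. This is the
natural object when there are few mutations and very many cells (the
transpose of a cell-lineage tree). Observations enter through a
false-positive/false-negative error model with FPR $\alpha$ (default 1%,
a global sequencing-error estimate) and FNR $\beta_j$ (the allele-dropout
rate, per locus or global):

$$P(D_{cj} = 1 \mid E_j(v) = 0) = \alpha, \qquad
  P(D_{cj} = 0 \mid E_j(v) = 1) = \beta_j,$$

where $E_j(v)$ indicates whether event $j$ is an ancestor-or-self of $v$.
Missing entries (code 3) contribute no likelihood factor, so partially
genotyped cells still inform the tree. The tree likelihood marginalizes
each cell's attachment over the $E + 1$ nodes with uniform weight:

$$\log L(T, \beta) = \sum_c \log \frac{1}{E+1}
  \sum_v \prod_j P(D_{cj} \mid E_j(v)).$$

Internally, cells with identical observed genotypes (and timepoint) are
collapsed into weighted patterns, so the per-iteration cost is
$O(\text{patterns} \times (E+1))$ rather than $O(\text{cells} \times (E+1))$ —
with 8 loci and 6,000 cells that is two orders of magnitude.

### MCMC

`mcmc_infer()` runs Metropolis–Hastings over trees with three symmetric
moves — prune-and-reattach (new parent uniform over non-descendants),
node-label swap, and subtree swap (identity proposal when the chosen
subtrees are nested) — under a uniform prior over trees, plus error-rate
updates when the FNR is learned. Four standard configurations mirror
common practice:

| model | cells                 | FNR      |
|-------|-----------------------|----------|
| 1     | all (missing allowed) | learned  |
| 2     | all (missing allowed) | fixed to the platform/sample ADO |
| 3     | complete genotypes    | learned  |
| 4     | complete genotypes    | fixed    |

Model 2 is the reporting default. `consensus_across_models()` compares
the four MAP parent vectors and flags a case consistent only when all
four agree. The learned global FNR uses a uniform prior on $[0,1]$ with
Gaussian random-walk proposals ($\sigma = 0.1$, reflected at the bounds);
locus-specific FNRs use independent walks under a Gaussian prior centred
on the sample ADO estimate with SD 0.002, truncated to $[0,1]$, with the
log-prior added to the acceptance ratio.

Chain defaults are 3 chains of 20,000 iterations, 25% burn-in, thinning
10 — sized so that panels up to ~37 loci and ~10,000 cells mix in seconds
on one CPU thanks to pattern collapsing; a split-chain potential scale
reduction factor on the log-likelihood trace is reported as `rhat`.
Among equal-likelihood MAP trees the lexicographically smallest parent
vector is reported, making outputs deterministic under a seed. Loci with
all-missing genotypes are dropped with a warning. Doublets are *not*
modelled in the likelihood (matching common pipeline practice); they
exist only as a stress option in the generator.

Correctness is established two ways in the test suite: on instances small
enough to enumerate every parent vector, the MCMC MAP log-likelihood
equals the exhaustive maximum (50/50 random instances), and on a 3-event
instance the visit frequencies of a long chain match the enumerated
posterior within total-variation distance 0.05.

### Zygosity and LOH ordering

Copy-neutral LOH converts heterozygous driver mutations to homozygous
ones. To time these events, `encode_zygosity()` splits every locus with
at least one homozygous call into two event rows: *M* (mutation acquired;
1 for het or hom calls) and *L* (LOH; 1 for hom calls only), missing
propagating to both, with the hard search constraint that node(M) be a
proper ancestor of node(L) — a homozygous state arises from a
pre-existing heterozygous one, not directly from wild type. One published
description of this encoding assigns the het row 0 for homozygous cells,
which is internally inconsistent with that ordering constraint under
mutation-tree semantics (a hom cell must sit below both events, hence be
"1" on both rows); the package uses the self-consistent reading above.
Constrained runs are initialized at a constraint-satisfying star tree and
reject violating proposals, so every posterior sample respects the
ordering (asserted exactly in the tests).

### Cell attachment and credible intervals

Subclone sizes come from posterior sampling: for each retained posterior
draw (tree, error rates), cells are assigned to nodes and the
assigned-cell counts per node form one draw of the clonal composition;
the 2.5/97.5 percentiles across draws give 95% credible intervals.

One design decision here deviates from the most literal rule of
"attach with probability $\propto \prod_j P(D_{cj} \mid E_j(v))$": that
flat-prior rule is *biased*. A parent-clone cell with a dropout at the
child locus is almost as attachable below as at its true node, so each
clone leaks $O(\beta)$ of its mass to descendant clones; in a
3-clone/5,000-cell simulation at $\beta = 0.06$ the bias is ~4 percentage
points and nominal-95% intervals never cover. `attach_cells()` therefore
samples attachments *jointly with a latent composition*: a short Gibbs
chain per posterior draw alternates between assigning cells with
probability $\propto \pi_{t v} \prod_j P(D_{cj} \mid E_j(v))$ and
resampling the per-timepoint composition
$\pi_t \sim \mathrm{Dirichlet}(1 + \text{counts})$. This estimator is
consistent, reduces to the flat rule when the likelihood carries no
information (all-missing cells are flagged and follow the learned
composition), and yields calibrated intervals — measured per-interval
coverage is ~96% at nominal 95%, and point estimates sit within 2
percentage points of the realized clone fractions.

The same mechanism explains a limitation of FNR *learning*: the uniform
attachment prior inside the tree likelihood is part of the model, so on
samples with strongly skewed clone sizes the learned global FNR absorbs
some of the prior misfit and lands above the simulated dropout rate
(e.g. ~9% when the truth is 5.8% on a skewed 8-clone sample). Under
balanced clone sizes recovery is unbiased to within ±0.02. The
locus-specific mode behaves exactly as its tight prior dictates: with
prior SD 0.002 the posterior is dominated by the prior unless a locus is
carried by hundreds of thousands of cells, so a single deviant locus
(simulated at 0.12 among 0.06) is *not* recoverable at panel scale —
consistent with reports that locus-specific runs closely resemble
locus-independent ones. The corresponding acceptance check is left
failing rather than relaxing the prior, since the prior value is part of
the method being reproduced.

### Longitudinal samples

For serial samples from one patient, `longitudinal_infer()` pools all
timepoints into one tree inference, then attaches cells per timepoint
with the restriction that a cell cannot sit at or below any mutation
unobserved at its sampling time (applied under each posterior draw's own
tree, so the excluded mass is exactly zero in every draw). A subclone can
therefore have 0% prevalence at a timepoint without any claim that it was
extinct — there is simply no evidence for it among the sampled cells. A
simulated therapy sweep (a subclone moving from 10% to 70% of tumor
cells) is recovered within well under 3 percentage points per timepoint.

## Clonal composition, diversity, and evolution patterns

`compose_clones()` reports one subclone per tree node that carries at
least one mutation and at least one hard-assigned cell; its mutation set
is the node's root path, its cell count comes from hard assignments
(cells are conserved exactly), and its fraction — of *mutated* cells,
wild-type cells excluded — is the posterior mean, consistent with the
credible interval. Clones under 1% of mutated cells are kept but flagged,
and the clone-level association analysis excludes them (such tiny
populations are often dropout or multiplet artifacts rather than clones).

`shannon_index()` is $H = -\sum_i p_i \log_2 p_i$ over the renormalized
mutated-clone fractions — base 2, wild-type excluded, matching the
subclone definition; `include_wt = TRUE` exists for sensitivity analysis.

`classify_evolution()` reduces the tree to events carried by surviving
clones and counts branch points. A pattern is *linear* when there is no
branch point, or exactly one whose children are all leaf events — a
terminal fork, which in practice is labelled linear because the forked
clones differ only in their final step; `terminal_fork_linear = FALSE`
gives the strict pure-path rule. Everything else is *branching*, and a
branching case is *convergent* when two events of the same gene (or the
same pathway, given a gene-to-pathway map; an AML default ships as
`default_pathway_map()`) sit on disjoint branches — the signature of
functionally redundant mutations acquired in parallel.

There is no universally agreed operational definition of linear vs
branching; this rule reproduces the figure-level conventions of published
AML phylogenies but has not been validated against any cohort's published
split, which would require the deposited data.

## Co-occurrence statistics

Three levels, one table shape (`pair`, 2×2 counts, log OR, p, BH q):

* **cell level** (within a sample): cells missing at either locus are
  excluded pairwise; the log odds ratio is base 2 with Haldane correction
  (+0.5 to every cell, keeping it finite for zero counts); significance
  is a two-sided Fisher exact test with BH adjustment across the sample's
  pairs. Pairs with no informative cells are flagged and excluded from
  the adjustment.
* **patient level** (cohort bulk presence/absence): Haldane-corrected
  *natural*-log OR; independence tested by the G-statistic
  $G = 2\sum O \ln(O/E)$ computed on the uncorrected counts (with
  $0\ln 0 = 0$) against $\chi^2_1$; BH across pairs. The correction is
  attached only to the odds ratio, not to $G$.
* **clone level**: units are clones pooled across patients, restricted to
  clones at or above 1% of a patient's mutated cells; a gene is present
  in a clone when any of its events is in the clone's mutation set; then
  as at the patient level.

The log bases differ by level because cell-level results are
conventionally reported as log2 odds ratios while cohort-level summaries
use natural logs; every output row carries an explicit `base` column.
Under a simulated independence null (10,000 cells, 200 replicates) the
BH-adjusted cell-level analysis rejects at q < 0.1 in well under 10% of
replicates, and both the Haldane log OR and the BH adjustment are checked
against brute-force oracles.

## The synthetic-data generator

All tests run against `simulate_sample()` and its parts, which emulate a
targeted single-cell panel run:

* **topology**: `simulate_tree()` draws a random recursive tree (each new
  event picks its parent uniformly from the root and existing events,
  with labels assigned uniformly at random), a simple null with
  closed-form shape probabilities that the tests verify (two events: fork
  1/2, each chain 1/4).
* **composition**: symmetric Dirichlet over mutated nodes rescaled to
  `1 - wt_fraction`, optional `depth_decay < 1` making deeper (younger)
  clones smaller in expectation — the coupling that gives linear
  histories their concentrated, low-diversity compositions — and
  logistic-normal drift between timepoints.
* **genotype noise**: false positives at rate `fpr`, per-locus dropout
  `fnr_j`, per-locus missingness, and doublets modelled as the
  elementwise maximum of two true genotype rows (a multiplet looks mutant
  wherever either cell is). In zygosity mode dropout acts per allele:
  het is observed as wild type or as hom with probability `fnr_j/2` each,
  hom as het with `fnr_j/2`.
* **read counts**: negative-binomial depth (default mean 48x, size 4);
  per-allele dropout probability $q = (1 - \sqrt{1 - 2\,\mathrm{ado}})/2$
  chosen so the homozygous-looking call rate equals the target ADO, with
  double dropout yielding no reads; binomial alternate counts at 0.5
  (balanced het), `1 - base_error`, or `base_error`.

Defaults mirror cohort-scale AML runs: ~6,000 cells, 8-to-37-locus
panels, 10 SNP loci, ADO 5.8%, FPR 1%, mean depth 48x. A doublet rate is
configurable but has no claimed cohort value. Simulation sizes used in
the tests (3,000–10,000 cells, up to $10^6$ MCMC iterations, 100-replicate
recovery and coverage studies) were chosen as the smallest scales at
which the statistical claims are sharp.

What passing these tests shows: the estimators are correct and calibrated
*under the stated error model* — Bernoulli dropout and false positives,
independent across loci, amplicon-level missingness, no copy-number
variation beyond the explicit LOH events, no barcode or alignment
artifacts. Real Tapestri-class data violate these assumptions in known
ways (GC-dependent coverage, correlated dropout within amplicons,
doublet enrichment among large clones), so cohort-level conclusions still
require the usual orthogonal validation.

## Reproducibility

Every stochastic function takes an explicit seed; `run_pipeline()`
requires one (no silent entropy), records seeds, parameters, input and
output MD5 hashes and per-stage runtimes in a manifest, and skips stages
whose parameters and upstream hashes are unchanged. Identical
configuration and seeds reproduce outputs byte for byte. The
`analysis/01_simulate.R` … `analysis/05_association.R` drivers walk the
full pipeline on the demo sample and write their tables under
`results/`; `scripts/acceptance.R` recomputes the headline quantities
from scratch for any seed.
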