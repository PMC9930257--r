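---
title: "Regulon activity landscapes and cell-specific networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulon activity landscapes and cell-specific networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscape)
```

This vignette is the package's account of its own methods: the models
and statistics it implements, the assumptions behind them, the numerical
choices made where the underlying ideas leave room, and what the
synthetic-data tests do and do not demonstrate about real data.

## The scientific setting

A *regulon* is a transcription factor together with the target genes it
co-regulates; the unit is switched on or off largely as a whole. In
single-cell RNA-seq of a differentiating lineage — the motivating case
is human osteoblasts progressing from preosteoblasts through an
intermediate state to mature osteoblasts — cell states are often better
separated by *which regulons are active* than by single marker genes,
and the wiring of each cell's own gene-association network changes along
the way. The package provides the analysis backbone for that view:
score regulon activity per cell, build a network per cell, order cells
in pseudotime, and test which programs and connections belong to which
state.

## Quality control and normalization

Cells are kept when they satisfy all of: detected genes within
[`min_genes`, `max_genes`] (defaults 200 and 5000 — a floor against
empty droplets and degraded cells, a ceiling against doublets);
mitochondrial count fraction at most `max_mito_frac` (default 0.15,
genes identified by the configurable symbol prefix `MT-`); raw count
> 0 for every required lineage marker (default *RUNX2*, "expressed"
interpreted as any nonzero count since no threshold is standard); and
raw count 0 for every exclusion gene (default the hemoglobin genes
*HBM*, *HBA1*, *HBA2*, *HBB*, flagging erythrocyte contamination). A
cell failing several rules is attributed to the first failing rule in
the fixed order low/high/mito/marker/excluded so reports are
reproducible. Normalization scales each cell to `scale_total` (default
10,000) counts and applies log1p; `sum(expm1(value))` per cell
reproduces the scale exactly, which the tests assert.

Highly variable genes are ranked by *standardized dispersion*: the
dispersion (variance/mean of log-normalized values) is z-scored within
20 equal-frequency bins of gene mean. Raw dispersion mostly ranks genes
by expression level; the binned z-score asks whether a gene is unusually
variable *for its level*, which is what isolates genuinely structured
genes. Constant genes are never selected. This is an approximation to
the variance-stabilizing fits used elsewhere; on the synthetic data it
recovers the planted structured genes, and `n_top` (default 2000) is a
parameter. PCA centers and unit-scales the chosen genes, keeps
`n_pcs` (default 18) components, and reports the full spectrum of
per-PC standard deviations so that the variance percentages
(stdev²/Σstdev²·100) sum to 100.

## Regulon activity: the recovery-curve AUC

Within each cell, genes are ranked by decreasing expression. Ties —
dominated by the zero block in sparse data — are broken by a seeded
random shuffle; without randomized tie-breaking the score of the zero
block would be ill-defined, and the recorded `tie_seed` makes the whole
matrix reproducible. For a gene set S in a universe of G genes, with
T = ⌈`top_frac`·G⌉ (default `top_frac` = 0.05):

- hits(t) = number of set genes with rank ≤ t,
- AUC = Σ_{t=1}^{T−1} hits(t) / Σ_{t=1}^{T−1} min(t, |S|).

The left-rectangle sum and the max-normalization define the score
exactly (variants exist, so the tests pin these choices); it lies in
[0, 1], equals 1 exactly when the set packs the top ranks, and is
invariant to any monotone transform of the cell's expression. Because
the score is competitive — only T ranks exist — strongly elevated gene
programs displace other genes from the top block; at realistic gene
counts (thousands) this displacement is negligible, but in very small
simulated universes it measurably depresses the scores of unrelated
sets, which is why the type-I tests for differential activity use a
2000-gene universe.

Differential activity across clusters uses the Kruskal–Wallis test
(expression and activity values are far from normal) with BH adjustment
across features and significance at adjusted p < 0.05.

## Cell-specific networks

For one cell *k* and one gene, the *box* is the window of the
m = ⌈`box_frac`·n⌉ cells nearest to *k* in midrank (default
`box_frac` = 0.1). Whole blocks of value-tied cells enter or leave
together (ties share a midrank), with the lower side preferred on
two-sided rank ties, so the box is well defined under heavy zero ties
and exceeds m cells only through ties; *k* is always a member. For a
gene pair the edge statistic is

ρ̂ = √(n−1)·(n·n_xy − n_x·n_y) / √(n_x·n_y·(n−n_x)·(n−n_y)),

the standardized co-occupancy of the two boxes, and an edge is called in
cell *k* when ρ̂ exceeds the upper-tail normal quantile at `alpha`
(default 0.01; one-sided, since edges denote positive association).

Two numerical choices matter and are fixed here deliberately:

1. **Focal-cell conditioning.** The focal cell sits in both of its own
   boxes by construction, which adds a deterministic unit of
   co-occupancy and biases the independence null upward (the empirical
   per-edge rate at α = 0.01 is ~0.05 without correction). The counts
   entering the formula therefore cover the other n−1 cells. With
   exact-size boxes on tie-free data the conditional null count is
   exactly hypergeometric, and the normal test calibrates: the closed
   form P(ρ̂ > z₀.₉₉) = 0.0140 at n = 500, matched by simulation.
2. **Expression gating.** A gene with zero expression in the focal cell
   has an empty neighborhood there: its edges are untestable (never
   significant) in that cell. Without the gate, any two genes that are
   *off together* share the zero tie-block and earn massive
   "co-silence" edges, which swamps the degree matrix in clusters where
   a program is inactive.

Degenerate boxes (constant genes) likewise make an edge untestable
rather than erroring the run. The network degree matrix NDM[g, k]
counts gene g's significant edges in cell k; Σ_g NDM[g, k] equals twice
the cell's edge count (asserted), and a two-sided Wilcoxon rank-sum
test with BH adjustment finds genes whose degree differs in one cluster
versus the rest. Subset networks (`gene_subset`) compute boxes over all
cells but only test pairs within the subset; all-pairs transcriptome
networks are supported but quadratic in gene count.

## Diffusion maps and pseudotime

Distances are Euclidean in the supplied space (expression PCs or the
activity matrix). The kernel is Gaussian with locally adaptive
bandwidth — σᵢ is the distance to the ⌈`k_neighbors`/2⌉-th neighbor
(default `k_neighbors` = 30) — which makes the transition matrix
invariant to global rescaling of the input (asserted numerically).
Density normalization divides the kernel by the product of its row
sums, removing sampling-density effects, before row-normalizing to a
Markov matrix. The symmetric conjugate is eigendecomposed (exact and
deterministic at these sizes); the trivial constant eigenvector is
dropped, components are eigenvalue-scaled eigenvectors, and each
component's sign is fixed by making its largest-magnitude entry
positive. Duplicate cells (zero bandwidth) are handled by flooring the
bandwidth at the smallest positive distance, with a warning — common
when many cells have identical all-zero activity.

Pseudotime is the diffusion-pseudotime construction: distance between
cells in the eigenspace weighted by λ/(1−λ) (summing transition kernels
over all path lengths), anchored at a root and rescaled to [0, 1]. A
disconnected kernel graph (a second unit eigenvalue) is an error at
this step, naming the offending components. The default root is the
cell most extreme on the first diffusion component within a user-named
early cluster: a cell chosen by external information (e.g. earliest
known state) can sit mid-cloud in the embedding and distort distances,
while the extreme-on-DC1 anchor is stable across simulations. Mean
cell-to-cell transition probabilities aggregated over cluster pairs
summarize lineage adjacency.

## Preranked GSEA

The running-sum statistic adds |stat|^p normalized over the set at hits
(weight `weight_p` = 1 by default; 0 gives the classic
Kolmogorov–Smirnov form) and subtracts 1/(N−|S|) at misses; ES is the
extremum by absolute value and the leading edge is the hits at or
before (positive ES) or after (negative ES) the extremum. The null is
gene-permutation — `n_perm` random same-size draws from the ranked
universe, seeded — matching preranked practice. NES divides ES by the
mean |null ES| of matching sign; p-values use the add-one correction
for sampled nulls (the observed score counts as a draw, so p is never
zero and the test is exact under exchangeability — without it the
type-I rate at the composite filter measurably exceeds its nominal
level). Significance requires BH-FDR < 0.05 *and* |NES| > 1. The
cluster-level ranking metric is the mean log-normalized expression
difference (cluster vs rest); set-size bounds default to 5/500.

## MCODE

Vertex weights below the degree cutoff (2) are zero; otherwise the
weight is the core-clustering coefficient of the closed neighborhood:
k_max times the density of the highest k-core of N[v]. Seeds are taken
in decreasing weight; modules grow by breadth-first traversal over
unvisited neighbors with weight ≥ seed weight · (1 − node score cutoff,
0.2); included vertices are marked visited, so modules are
vertex-disjoint. A module must contain a 2-core; its score is density ×
|V| (so any clique K_n scores exactly n, asserted for n = 3..8), and
modules at or above the score cutoff (3.0) form the primary list with
the remainder retained separately. Edge weights (combined scores) are
used only for optional input filtering and display — the algorithm
itself is topological. Fluff and haircut post-processing exist but are
off by default.

## The synthetic-data generator

The generator is the ground truth for every stage. Defaults define the
study conditions used throughout the tests and the acceptance script: 3
clusters × 200 cells, 200 background genes, two planted ten-target
regulons (one active in the earliest cluster, one in the latest),
negative-binomial counts with mean 2 and size 2, fold change 8 in
active clusters, logistic dropout with midpoint 0 and slope 1 (≈33%
zeroing at the baseline mean, ≈6% at the activated mean), ten
marker-up and ten marker-down genes with trend coefficient 3, and a
latent pseudotime drawn stratified-uniform so that clusters are exactly
its equal-width bins. These sizes keep every recovery test inside a few
seconds while leaving all planted effects comfortably detectable; the
fold change of 8 reflects the strong on/off contrast of a regulon
rather than a subtle shift.

QC decoys add `MT-` genes (≈5% of counts in good cells, capped
deterministically at 12% so the truth flag is exact), silent hemoglobin
genes, a guaranteed-detected *RUNX2*, and bad cells that each violate
exactly one rule (too few genes, too many genes, ~50% mitochondrial
mass, missing *RUNX2*), cycled in that order. The planted-clique graphs
put uniform [0.4, 1] weights on an Erdős–Rényi background and ≥0.9
weights inside cliques.

What the generator does *not* emulate: batch effects, ambient RNA,
doublet expression mixtures, UMI-level noise, graded (non-binary)
regulon activity, or the 20,000-gene scale of real transcriptomes.
Passing tests therefore demonstrate correctness of the statistics and
recoverability under clean planted signal — not performance on real
tissue. Two desk-scale artifacts are handled explicitly: AUC
competition in small universes (see above) and co-silence edges in CSN
(gated).

## Problem sizes and runtime

The default test and acceptance computations use: 600-cell datasets for
recovery; n = 500 × 10 genes × 10 seeds for CSN null calibration (the
rate is compared with its hypergeometric closed form); 2000-gene lists
with 1000 permutations for GSEA power and 200 × 200-permutation
replicates for the type-I rate (the unit suite uses 2000 replicates for
a tighter binomial bound on the same ≤5% property); and 59-node graphs
for MCODE recovery. Everything runs in well under two minutes on one
CPU.

## Known limitations

- The CSN builder stores one n × n box indicator per gene; memory grows
  as G·n², so transcriptome-wide runs need chunking (the per-pair
  computation is independent and trivially chunkable).
- The k-means clusterer is a baseline; graph-based community detection
  is deliberately out of scope, and external labels are accepted
  everywhere labels are consumed.
- Branch assignment on bifurcating lineages is not implemented; the
  generator can emit a two-branch flag for visual inspection only.
- NES for sets with no same-sign null draws is reported as ±Inf with
  p = 1/(n_perm + 1); this occurs only for pathological rankings.
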