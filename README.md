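# regulonscape

Tools for characterising **transcription-factor regulon activity
landscapes** in single-cell RNA-seq data, with an emphasis on the network
view of cell state: which co-regulated gene programs are switched on in
which cells, how strongly each gene is wired into its cell's own
association network, and how both change along a developmental
trajectory such as the osteoblast lineage (preosteoblast → intermediate →
mature osteoblast).

The package implements, end to end and with synthetic ground truth for
every stage:

- **QC and normalization** — detected-gene bounds, mitochondrial
  fraction ceiling, lineage-marker selection (e.g. *RUNX2*+) and
  hemoglobin exclusion; per-cell scaling to 10,000 counts with log1p.
- **Regulon activity scoring** — per cell, genes are ranked by
  expression and a regulon (TF + target set) is scored by the area under
  its gene-set recovery curve over the top 5% of ranks, an
  AUCell-style statistic that is robust to dropout because it only uses
  ranks.
- **Cell-specific networks (CSN)** — for every cell *k* and gene pair
  (*x*, *y*), boxes of the ~0.1·n nearest cells in each gene's expression
  are intersected and the standardized co-occupancy

  ρ̂ₓᵧ⁽ᵏ⁾ = √(n−1) · (n·nₓᵧ − nₓ·nᵧ) / √(nₓ·nᵧ·(n−nₓ)·(n−nᵧ))

  is tested against N(0, 1); the **network degree matrix** (NDM) counts
  each gene's significant edges per cell, and a Wilcoxon rank-sum test
  finds genes differentially connected in one cluster versus the rest.
- **Diffusion-map pseudotime** — locally scaled Gaussian kernel, density
  normalization, eigen-decomposition of the cell-to-cell transition
  matrix, diffusion-pseudotime distances anchored at a root cell, and
  mean cluster-to-cluster transition probabilities. Works on expression
  PCs or directly on the regulon activity matrix.
- **Preranked GSEA** — weighted Kolmogorov–Smirnov enrichment scores,
  gene-permutation NES and FDR, with the significance filter
  FDR < 0.05 and |NES| > 1.
- **MCODE** — dense-module detection on weighted interaction graphs
  (vertex weighting by core-clustering coefficient, seeded outward
  growth; defaults: degree cutoff 2, node score cutoff 0.2, K-core 2,
  score cutoff 3.0).
- **Synthetic data** — negative-binomial counts with logistic dropout,
  planted regulons active in designated clusters, monotone marker genes
  along a latent pseudotime, decoy mitochondrial/hemoglobin genes, cells
  that each violate exactly one QC rule, and background graphs with
  planted cliques — so every stage above can be checked against ground
  truth.

## Worked example

```r
library(regulonscape)

ds <- simulate_counts(sim_config(seed = 1, n_qc_bad_cells = 12,
                                 include_decoy_genes = TRUE))
ds
#> synthetic_dataset: 612 cells x 215 genes; 3 clusters; 2 planted regulons;
#> 12 planted low-quality cells

qf <- qc_filter(ds$counts, ds$qc_params)
str(qf$report[1:5])
#> $ low: 3   $ high: 3   $ mito: 3   $ marker: 3   $ excluded: 0
```

The twelve planted low-quality cells are removed, three per violated
rule, and nothing else. Scoring the two planted regulons and averaging
per cluster:

```r
norm  <- normalize_log(qf$counts)
ranks <- rank_genes_per_cell(norm, tie_seed = 1)
act   <- score_all(ranks, ds$regulon_truth$regulons)
round(summarize_by_cluster(act, ds$true_labels[qf$keep]), 3)
#>   G0001 G0012
#> 1 0.704 0.002
#> 2 0.018 0.019
#> 3 0.003 0.707
```

Each regulon's activity peaks exactly in its planted cluster (G0001 in
cluster 1, G0012 in cluster 3). The cell-specific network over the first
regulon's genes, and the genes most differentially connected in its
active cluster:

```r
cs <- build_csn(norm, csn_params(gene_subset = c("G0001",
                                                 sprintf("G%04d", 2:11))))
cs
#> csn_result: 11 genes x 600 cells; 5388 significant edge calls
#> (alpha = 0.01, box_frac = 0.1)

dn <- differential_ndm(ndm(cs), ds$true_labels[qf$keep], 1)
head(dn[order(dn$p_adjusted), c("gene", "mean_in", "mean_out",
                                "p_adjusted")], 3)
#>        gene mean_in mean_out   p_adjusted
#> G0008 G0008   4.750   0.0675 1.630977e-78
#> G0005 G0005   4.805   0.1350 1.237310e-72
#> G0003 G0003   4.935   0.2000 1.262296e-71
```

Regulon members carry ~5 significant edges per cell inside the active
cluster and essentially none outside it. Finally, diffusion pseudotime
from the expression PCs recovers the planted ordering:

```r
hvg <- select_hvg(norm, min(2000, ncol(norm)))
pca <- run_pca(norm, hvg, n_pcs = 18)
dm  <- diffusion_map(pca$embedding)
dm  <- diffusion_pseudotime(dm, select_root_cell(dm,
                              ds$true_labels[qf$keep], 1))
cor(dm$pseudotime, ds$true_pseudotime[qf$keep], method = "spearman")
#> 0.918
```

A single-config pipeline (`validate_config()` / `run_pipeline()`, or the
thin CLI at `inst/cli/regulonscape.R`) chains all stages with per-stage
child seeds, TSV outputs and a JSON run report; reruns are byte-identical.

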