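# agemyo

Analysis toolkit for the bespoke statistical stages of two-age-group
(adult vs old) single-cell and single-nucleus studies of skeletal muscle:

* **Heterogeneity ("transcriptional noise")** — per-cell Euclidean distance
  to the own-group centroid over expression-invariant genes, after matching
  the two age groups in cell number *and* per-cell sequencing depth
  (multivariate-hypergeometric downsampling). The same machinery runs on
  rounded snATAC gene-activity scores as the epigenetic arm. Group medians
  are compared with an exact/tie-corrected two-tailed Mann–Whitney U-test.
* **Myofibre typing** — expression-matched module scores for the type I,
  pan type II, IIA and IIX marker panels, followed by a two-tier
  hierarchical classifier (type I / type II / hybrid I–IIA, then IIA / IIX /
  hybrid IIA–IIX) on z-standardized scores, with per-individual proportion
  summaries and Mann–Whitney group comparisons.
* **Composition** — a Poisson generalized linear mixed model for per-sample
  cell-type counts,
  `log λ_sc = log N_s + μ + α_c + Σ_f β_{f(s),c} + u_s`, with grand-mean
  (doubly sum-to-zero) coding of every cell-type × factor interaction,
  adaptive shrinkage of each factor's effects, and the **LTSR** (local true
  sign rate, `max(P(β>0), P(β<0))`) as the evidence measure. Laplace and
  MCMC inference backends cross-check each other.
* **Trajectory trends** — equal-count binning of a supplied pseudotime
  (100 bins), per-bin age-group occupancy, module scores along the
  trajectory, variable-gene selection on binned trends, and k-means++
  gene-trend clustering with peak-ordered centroids.
* **Synthetic atlas generator** — negative-binomial counts with cell-type
  and fibre-type marker programs, hybrid myonuclei, age-tilted abundances,
  group-specific overdispersion and an age-ordered latent degeneration
  pseudotime, plus ground-truth labels, so every stage is testable with no
  sequencing data. A gamma-distributed gene-activity generator mirrors the
  chromatin arm.

The package is aimed at computational biologists who already have a
QC-ready count matrix (plus cell/sample metadata and, optionally, a
pseudotime) and need the downstream ageing-specific statistics. Upstream
work — alignment, doublet/ambient cleanup, integration, clustering,
annotation, trajectory inference — is deliberately out of scope.

## Worked example

```r
library(agemyo)

cfg <- simConfig(seed = 7)              # 12 samples/group x 500 cells, 2,000 genes
sce <- qcFilter(generateAtlas(cfg))     # UMIs > 1,000, genes > 500, mito < 5%
unlist(S4Vectors::metadata(sce)$qc[1:5])
#> n_before  n_after  removed_low_umi  removed_low_genes  removed_high_mito
#>    12000    10738               51                 15               1217

noisePerCell(sce, "MuSC", nMax = 300, seed = 7)
#> NoiseResult for cell type 'MuSC': 354 cells, 200 invariant genes
#>   median adult 15.35 | median old 16.13 | U = 7218.0 | p = 1.74e-18

cc  <- buildCounts(SummarizedExperiment::colData(sce), sampleData(sce))
fit <- fitPoissonGLMM(cc, factors = c("age_group", "sex", "ethnicity",
                                      "modality", "batch"))
res <- compositionEffects(summarizeLTSR(fit))
res[res$factor == "age_group" & res$level == "old" &
    res$cell_type %in% c("MuSC", "Macrophage", "FAP", "Myofibre"), ]
#>    cell_type    factor level  log_fc fold_change  ltsr  ci_low  ci_high
#>          FAP age_group   old  0.0834       1.087 0.999  0.0332  0.13368
#>   Macrophage age_group   old  0.1304       1.139 1.000  0.0633  0.19752
#>         MuSC age_group   old -0.1556       0.856 1.000 -0.2359 -0.07524
#>     Myofibre age_group   old -0.0314       0.969 0.984 -0.0602 -0.00259
```

Reading the output: the QC report counts cells failing each criterion (a
cell can fail several). The noise result says old-group MuSC transcriptomes
sit further from their own centroid than adult ones (higher median
distance, two-tailed Mann–Whitney p ≈ 2e-18) — the generator simulates a
doubled old-group dispersion, and the statistic detects it. The composition
table reports grand-mean-relative fold changes with their LTSR: muscle stem
cells are depleted in the old group (fold change 0.86, LTSR ≈ 1) while
macrophages and fibro-adipogenic progenitors expand, matching the
configured abundance tilts (estimates are shrunken toward zero by design).

A pseudotime trend analysis continues from the same object:

```r
sce <- normalizeLog1p(sce)
tr  <- simTruth(sce)                         # pseudotime is an input column
pt  <- setNames(tr$pseudotime_true, tr$cell_id)
pt  <- pt[!is.na(pt)]                        # myonuclei only
bins <- binPseudotime(pt, 100)
bm   <- aggregateBins(SummarizedExperiment::assay(sce[, names(pt)],
                                                  "logcounts"), bins)
tc   <- clusterGeneTrends(bm, selectVariableGenes(bm, 500), k = 10, seed = 7)
```

A thin command-line dispatcher over the same functions ships in
`inst/scripts/agemyo.R` (`simulate`, `qc`, `noise`, `fibretype`,
`composition`, `trends` subcommands).

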