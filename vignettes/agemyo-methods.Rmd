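---
title: "agemyo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{agemyo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`agemyo` implements the bespoke computational stages of a two-age-group
(adult vs old) single-cell / single-nucleus analysis of human skeletal
muscle: per-cell transcriptional and epigenetic heterogeneity ("noise")
after matched downsampling, marker-module scoring with hierarchical
myofibre-type classification of myonuclei, Poisson-GLMM cell-type
composition analysis with local true sign rates, and pseudotime bin/trend
analysis. Upstream processing (alignment, doublet and ambient-RNA removal,
integration, clustering, annotation, trajectory *inference*) is out of
scope: the package starts from a count matrix, cell and sample metadata,
and — for the trajectory stage — a per-cell pseudotime supplied as input.

The central container is a `SingleCellExperiment`: the counts (or
gene-activity scores) as an assay, per-cell metadata in `colData`, and the
sample-level covariate table in `metadata(sce)$samples`. A synthetic-data
generator (`generateAtlas()`, `generateGeneScores()`) reproduces the
statistical structure every downstream stage assumes, with ground-truth
labels, so the whole pipeline is testable without access to sequencing
data.

# The synthetic atlas

Counts are negative binomial, parameterized as mean $\mu$ and dispersion
$\phi$ with $\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$ degenerates to
Poisson. This is the standard overdispersed noise model for UMI counts, and
$\phi$ is exactly the knob the heterogeneity statistic must detect. Each
cell's expected profile is a gene-weight vector (lognormal baseline):

* cell-type marker genes (10 per type) are elevated `markerEffect`-fold
  (default 4) in their own type;
* myonuclei additionally carry the four shipped fibre-type panels: the pan
  type I program in type I nuclei, the pan type II program plus the IIA or
  IIX subtype panel in fast nuclei. Hybrid myonuclei (`hybridFrac`, default
  10%) are 50/50 mixtures of the two parent mean vectors, mimicking nuclei
  co-expressing two myosin heavy-chain genes;
* a latent degeneration pseudotime $t \in [0,1]$ modulates trend genes via
  four archetypes: monotone up ($1 + 2t$), monotone down ($3 - 2t$),
  late-abrupt up (logistic step centred at $t = 0.8$), and flat. Adult
  nuclei draw $t \sim \mathrm{Beta}(1.5, 3)$, old nuclei
  $t \sim \mathrm{Beta}(3, 1.5)$, so occupancy along the trajectory is
  age-ordered;
* per-cell library sizes are lognormal (default median 2,500 UMIs,
  $\sigma = 0.35$ on the log scale) and a Beta(2, 80) mitochondrial
  fraction (mean ≈ 2.4%) assigns expected mass to the `MT-` gene block (the
  first 1% of gene ids), so the QC stage has realistic work to do;
* per-sample cell-type counts are multinomial; the old group's proportions
  are tilted by `exp(ageEffects)`. Defaults emulate the qualitative ageing
  portrait of the tissue: fewer muscle stem cells and IIX/IIA myonuclei,
  more immune and stromal cells, and a doubled old-group dispersion
  ($\phi$: 0.4 adult, 0.8 old). Effect sizes for the dispersion difference
  are not published anywhere we can cite numerically; the 2x default was
  chosen once as a clearly detectable but not degenerate working condition
  and is exposed in `simConfig()`.

Sex, ethnicity, sequencing batch and modality are assigned round-robin
across samples so the composition model always has covariates to adjust
for. `markerEffect = 1` is allowed and produces the no-signal control used
in tests.

What the generator does **not** emulate: doublets, ambient RNA,
batch-specific expression shifts, integration artefacts, zero-inflation
beyond the NB, or chromatin fragment files (the epigenetic arm starts from
a gene-activity score matrix, simulated as gamma variates with the same
mean/dispersion structure). Tests passing on this fixture therefore
demonstrate correctness of the algorithms under their stated assumptions,
not robustness to those artefacts.

# Matrix IO, QC and downsampling

The exchange format is MatrixMarket coordinate triplets plus TSV sidecars
(`genes.tsv`, `cells.tsv`, `samples.tsv`, `truth.tsv`) and a JSON manifest
echoing the seed and configuration; `writeFixture()` / `readAtlas()`
round-trip losslessly and byte-identically for a fixed seed.

`qcFilter()` keeps cells with total counts **strictly** above `minUMI`
(default 1,000), **strictly** more than `minGenes` detected genes (count
> 0; default 500) and a mitochondrial fraction **strictly** below
`maxMitoFrac` (default 5%). The strict inequalities are a deliberate,
documented reading of the thresholds; boundary cells are removed. The
filter is idempotent and never touches the gene list.

`normalizeLog1p()` scales each cell to `targetSum` (default 10,000, the
de-facto community scale) and applies $\ln(1 + x)$.

Two downsampling primitives drive the depth matching:

* `downsampleCells()` — simple random sample without replacement down to a
  cap; sets already at or below the cap are returned whole.
* `downsampleCounts()` — each cell's counts are replaced by a
  **multivariate hypergeometric** draw of exactly `targetTotal` molecules
  without replacement. Binomial thinning would only match depth in
  expectation; the hypergeometric guarantees *exactly* equal totals, which
  is what the matched design requires. Consequences that tests rely on:
  totals equal the target exactly, no entry exceeds its original value,
  and zeros stay zero.

# The heterogeneity ("noise") statistic

For one cell type with both age groups present, `noisePerCell()` runs:

1. downsample each group to at most `nMax` cells (default 300; smaller
   groups keep all cells);
2. equalize cell numbers across groups (minimum of the two);
3. downsample every retained cell to the common minimum total count, so
   depth is identical everywhere;
4. log-normalize;
5. select invariant genes: expressed genes (mean > 0) are ranked by mean
   expression into 10 near-equal blocks and the lowest-CV 10% of each
   block is kept. Selection is performed **jointly** on the pooled matched
   matrix — per-group selection would let the gene set itself differ
   between groups and contaminate the comparison;
6. each cell's heterogeneity is its Euclidean distance, over the invariant
   genes, to the centroid of its own (cell type x age group) population.

Group medians are compared with a two-tailed Mann-Whitney U-test. The
per-cell distance-to-centroid definition is the default because the
statistic is reported per cell (box plots per group); a mean-pairwise
distance variant is available via `method = "pairwise"`. Distances are
computed on log-normalized, depth-matched counts — raw-count distances
would be dominated by residual depth differences, defeating the matching.

Determinism and symmetry received special care: every random choice is
seeded, and seeds are attached to the *physical cell sets* (ordered by
smallest cell id), not to the group labels, so relabelling the two groups
leaves every distance unchanged and maps $U \mapsto nm - U$ exactly.

`epigeneticNoisePerCell()` applies the identical pipeline to the
gene-activity score matrix after rounding it to integers. Rounding is
half-away-from-zero (2.5 → 3, −2.5 → −3): the rounding rule is not
standardized across languages and locales, so one locale-independent rule
is fixed and documented.

`mannWhitneyU()` computes $U = \sum_{i,j} [x_i > y_j] + \frac12 [x_i =
y_j]$. For $n + m \le 12$ the two-sided p value is exact, by enumerating
all $\binom{n+m}{n}$ assignments of the pooled midranks (ties handled
exactly); otherwise a normal approximation with tie-corrected variance and
continuity correction is used. The per-cell-type test at 300 + 300 cells is
approximately calibrated; distances within a group share an estimated
centroid and a jointly selected gene set, so cells are not perfectly
independent, and simulation places the null rejection rate near — not
exactly at — the nominal level.

# Fibre typing

`moduleScore()` implements the classic expression-matched control scheme:
genes are split into `nBins = 25` equal-count bins of average expression;
for each panel gene, `nCtrl = 100` control genes are sampled from its bin
(panel genes themselves are excluded from the control pool, which makes the
score exactly zero when panel and controls coincide and exactly $k$ when a
panel sits uniformly $k$ units above its bin mates). The score is the mean
normalized expression of the panel minus the mean of the pooled control
draw; sampling is without replacement unless a bin is smaller than
`nCtrl`. The defaults are the widely used values of this scoring scheme;
no parameters for it are published for this application.

`classifyFibreTypes()` z-standardizes each panel's scores across cells and
applies a two-tier rule. Tier 1: `unclassified` if
$\max(z_I, z_{II}) < \tau$; `hybrid I/IIA` if both $z_I$ and $z_{IIA}$
reach $\tau$ and differ by less than $\delta$; otherwise the larger of
$z_I, z_{II}$. The hybrid test precedes the argmax — after it, a hybrid
nucleus would always lose to one parent and the class would be
unreachable. Tier 2 subdivides type II the same way with the IIA/IIX
panels. Defaults $\tau = 0$, $\delta = 0.5$: z-standardization makes both
thresholds dimensionless, and the published description of the decision
tree names no cutoffs, so both are exposed as parameters and the shipped
values were fixed once against the synthetic atlas's learnability
invariant (≥ 90% pure-class recovery at `markerEffect = 4`). Ties in the
argmax go to the more oxidative class (I, then IIA); they have measure
zero on real scores but make the classifier a total function. Because the
cutoffs are not the published ones, per-class proportions on real data are
comparable only qualitatively, not numerically.

`fibreProportions()` and `compareProportions()` produce per-sample,
per-class proportions (six classes, summing to one per sample) and the
two-tailed Mann-Whitney comparison between age groups.

# Composition: Poisson GLMM and LTSR

Counts of cell type $c$ in sample $s$ are modelled as

$$y_{s,c} \sim \mathrm{Poisson}(\lambda_{s,c}), \qquad
\log \lambda_{s,c} = \log N_s + \mu + \alpha_c +
\textstyle\sum_f \beta_{f(s),c} + u_s,$$

with the per-sample total $N_s$ as offset and a sample random intercept
$u_s \sim N(0, \sigma^2)$, $\sigma \sim$ Half-Normal(1). Every cell-type x
factor interaction uses doubly sum-to-zero (grand-mean) coding: within
each factor level the effects sum to zero across cell types, and within
each cell type across levels. Each $\beta_{l,c}$ is therefore the log fold
change of cell type $c$ under level $l$ *relative to the grand mean*, and
`summarizeLTSR()` reports `exp(posterior mean)` as the fold change. A
practical consequence: a scenario like "one cell type doubles, the rest
stay put" is not itself a grand-mean-coded truth — its coded estimand
spreads across all cell types. Validation simulations therefore draw from
the model's own estimand (a sum-to-zero effect vector of magnitude
$\ln 2$).

The interaction effects of each factor share an adaptive scale,
$\beta_f \sim N(0, \tau_f^2)$ with $\tau_f \sim$ Half-Normal(1.5)
estimated from the data (a fixed scale can be forced via `priorBeta`).
This mirrors treating the interactions as random effects and is what
keeps the LTSR honest: with a fixed weakly-informative prior and strong
data, the posterior $z$-score is simply calibrated Gaussian and
$P(\mathrm{LTSR} > 0.9) \to 0.2$ under the null, which would make large
LTSR values routine; with the adaptive scale, a factor carrying no signal
collapses its $\tau_f$ and pulls every effect to zero (measured null rate
of LTSR > 0.9 ≈ 0.10 at 20 samples/group). Cell-type main effects get
$\alpha_c \sim N(0, 3^2)$.

Inference comes in two backends that cross-check each other:

* **Laplace** (default): penalized Newton-Raphson for the conditional
  mode, with $(\sigma, \tau_f)$ profiled on the Laplace-approximate
  marginal likelihood; the Gaussian approximation at the mode supplies
  means, LTSR ($\Phi(|m|/s)$) and normal credible intervals. Fast enough
  for hundreds of replicate fits.
* **MCMC**: preconditioned random-walk Metropolis over all coefficients
  plus the log variance parameters, with the proposal shaped by the
  Laplace covariance and its scale adapted to ≈ 0.234 acceptance during
  burn-in. LTSR and intervals come from the draws.

The `LTSR` is $\max(P(\beta > 0), P(\beta < 0)) \in [0.5, 1]$ — the
posterior probability that the estimated direction is correct.
Non-convergence of the Newton iteration is reported through the
`converged` flag and diagnostics, never silently. `simpleProportions()`
provides the model-free alternative (population shares per sample or per
dataset/modality).

The interaction-only design (no factor main effects) is intentional: a
factor's effect on the *total* cell yield is absorbed by the offset and
the sample intercept; only its effect on *composition* is identified, and
that is the interaction.

# Trajectory trends

Given a per-cell pseudotime (an input column, never inferred here),
`binPseudotime()` ranks cells (ties broken by cell id) and splits them
into `nBins = 100` equal-count bins whose sizes differ by at most one.
Equal-count bins guarantee no bin is empty and make the whole pipeline
invariant to strictly monotone reparameterizations of pseudotime;
equal-width bins would offer neither. `aggregateBins()` averages
normalized expression per bin; `selectVariableGenes()` ranks genes by the
variance of the binned trend (default top 4,000; ties by gene id). The
variance ranking operates on bin-level trends rather than cell-level
expression — the quantity being clustered is the trend, and bin-level
variance is the matching selection criterion.

`clusterGeneTrends()` z-scores each gene's trend across bins (otherwise
k-means groups by expression magnitude, not shape), then runs k-means with
k-means++ seeding and `nInit = 10` restarts, keeping the lowest inertia;
clusters are relabelled by the bin at which their centroid peaks so
cluster 1 always peaks earliest. Defaults `nBins = 100`, `nTop = 4000`,
`k = 10` are the published working sizes of this analysis; `nInit` is a
stability choice. `groupProportionPerBin()` and
`panelScoreAlongTrajectory()` produce the per-bin age occupancy and
module-score profiles; the bin score is exactly the mean of the per-cell
scores in the bin.

# Validation problem sizes

The shipped tests exercise the stages at deliberately desk-scale sizes,
chosen once as the package's working conditions: noise power/calibration
at 300 cells per group and 500 genes (100 and 200 replicates); fibre
typing on a 5,000-myonucleus atlas; composition at 20 samples per group
with five cell types (recovery, plus 200-replicate null calibration);
trend recovery on 100-bin two-archetype fixtures; and a 50,000-cell draw
for the proportion-convergence invariant. `scripts/acceptance.R` re-runs
the same computations end to end from a caller-supplied seed.

# Known limitations

* The hybrid/unclassified cutoffs ($\tau$, $\delta$) and the module-score
  parameters are package defaults, not published values; real-data
  proportions can be compared qualitatively only.
* The noise statistic's Mann-Whitney test is mildly approximate at the
  per-cell level (shared centroid and gene selection induce weak
  dependence between cells).
* The Poisson GLMM assumes counts conditionally independent given the
  sample intercept; strong within-sample clustering of cell capture would
  require a richer variance structure.
* The generator's NB/gamma families cannot represent modality-specific
  artefacts; modality enters only as a covariate label.
* MCMC uses a single chain with an adaptive-then-frozen scale; for final
  analyses at scale, longer chains and convergence checks on
  `diagnostics$mcmc_acceptance` are advisable.
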