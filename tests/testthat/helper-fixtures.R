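# Shared fixtures and independent oracles for the test suite.

# Brute-force Mann-Whitney U by explicit pair counting (no ranks).
mwOracleU <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Exact two-sided p by enumerating every assignment of the pooled values.
mwOracleP <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  uObs <- mwOracleU(x, y)
  combos <- utils::combn(N, n)
  us <- apply(combos, 2L, function(ix) mwOracleU(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= uObs + eps), mean(us >= uObs - eps)))
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

# Single-cell-type config for the noise pipeline studies.
noiseConfig <- function(seed, phiAdult = 0.4, phiOld = 0.8,
                        nCells = 300L, nGenes = 500L) {
  simConfig(nSamplesPerGroup = 1L, nCellsPerSample = nCells, nGenes = nGenes,
            cellTypeProps = c(MuSC = 1),
            ageEffects = stats::setNames(numeric(0), character(0)),
            dispersionAdult = phiAdult, dispersionOld = phiOld,
            pseudotimeTrendGenes = c(up = 0L, down = 0L, abrupt = 0L,
                                     flat = 0L),
            seed = seed)
}

# Myonucleus-only config for fibre-typing studies.
myoConfig <- function(seed, nSamples = 2L, nCells = 500L, markerEffect = 4,
                      phi = 0.4, hybridFrac = 0.1, nGenes = 1000L,
                      ageEffects = c(IIX = -0.5, IIA = -0.2)) {
  simConfig(nSamplesPerGroup = nSamples, nCellsPerSample = nCells,
            nGenes = nGenes, cellTypeProps = c(Myofibre = 1),
            ageEffects = ageEffects,
            dispersionAdult = phi, dispersionOld = phi,
            markerEffect = markerEffect, hybridFrac = hybridFrac, seed = seed)
}

# Composition fixture sampled from the model's own estimand: expanded
# old-group effect +effect for ct1 and -effect/4 for the other four types
# (sum-to-zero), mirrored with opposite sign in the adult group.
compositionFixture <- function(nPerGroup, effect, seed, cellsPerSample = 400L) {
  set.seed(seed)
  types <- paste0("ct", 1:5)
  beta <- c(effect, rep(-effect / 4, 4))
  sm <- S4Vectors::DataFrame(
    sample_id = sprintf("s%02d", seq_len(2L * nPerGroup)),
    age_group = rep(c("adult", "old"), each = nPerGroup))
  cells <- do.call(rbind, lapply(seq_len(2L * nPerGroup), function(i) {
    sgn <- if (sm$age_group[i] == "old") 1 else -1
    p <- exp(log(0.2) + sgn * beta)
    p <- p / sum(p)
    ct <- sample(types, cellsPerSample, replace = TRUE, prob = p)
    data.frame(cell_id = sprintf("s%02d_c%04d", i, seq_len(cellsPerSample)),
               sample_id = sm$sample_id[i], cell_type = ct)
  }))
  buildCounts(cells, sm)
}

# Tiny SingleCellExperiment around an explicit count matrix, one sample per
# age group, for direct noise-pipeline tests.
twoGroupSCE <- function(adultCounts, oldCounts, cellType = "MuSC") {
  m <- cbind(adultCounts, oldCounts)
  nA <- ncol(adultCounts)
  nO <- ncol(oldCounts)
  colnames(m) <- sprintf("c%03d", seq_len(nA + nO))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  cd <- S4Vectors::DataFrame(
    cell_id = colnames(m),
    sample_id = rep(c("A01", "O01"), c(nA, nO)),
    cell_type = cellType,
    modality = "snRNA",
    row.names = colnames(m))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = cd)
  S4Vectors::metadata(sce)$samples <- S4Vectors::DataFrame(
    sample_id = c("A01", "O01"), age_group = c("adult", "old"))
  sce
}

# QC toy from the worked example: totals {900, 1001, 1500, 2000, 3000},
# detected genes {400, 501, 600, 700, 800}, mito counts giving
# {1, 1, 6, 1, 1}% (cell 2 at 0.999% from integer rounding).
qcToySCE <- function() {
  totals <- c(900, 1001, 1500, 2000, 3000)
  nGenesDet <- c(400, 501, 600, 700, 800)
  mitoCounts <- c(9, 10, 90, 20, 30)
  G <- 900L
  genes <- c("MT-1", sprintf("G%03d", seq_len(G - 1L)))
  cols <- lapply(1:5, function(j) {
    v <- numeric(G)
    v[1L] <- mitoCounts[j]
    nOther <- nGenesDet[j] - 1L
    rest <- totals[j] - mitoCounts[j]
    v[2L:(1L + nOther)] <- 1
    v[2L] <- rest - (nOther - 1L)
    v
  })
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  colnames(m) <- paste0("cell", 1:5)
  cd <- S4Vectors::DataFrame(cell_id = colnames(m), sample_id = "s1",
                             cell_type = "A", modality = "snRNA",
                             row.names = colnames(m))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = cd)
}
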