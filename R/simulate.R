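#' @include AllClasses.R
NULL

.MYO_LABEL <- "Myofibre"
.FIBRE_CLASSES <- c("I", "IIA", "IIX", "hybrid I/IIA", "hybrid IIA/IIX")

#' Construct a synthetic-atlas configuration
#'
#' Builds a validated [SimConfig] with defaults emulating a two-group
#' (adult vs old) multi-individual skeletal-muscle atlas: 15 cell types
#' dominated by myonuclei, fibre-type marker programs (type I / IIA / IIX
#' plus 50/50 hybrid mixtures), old-shifted degeneration pseudotime with
#' monotone and late-abrupt gene trends, and higher old-group overdispersion.
#'
#' @param nSamplesPerGroup samples (individuals) per age group.
#' @param nCellsPerSample cells drawn per sample.
#' @param nGenes gene-universe size; the first `ceiling(0.01 * nGenes)` ids
#'   are mitochondrial (`"MT-"` prefix).
#' @param cellTypeProps named baseline cell-type proportions (sum to 1).
#' @param ageEffects named old-vs-adult abundance log-fold-changes; names may
#'   be cell types or fibre classes (see [SimConfig]).
#' @param dispersionAdult,dispersionOld negative-binomial dispersion
#'   \eqn{\phi} per age group, recycled across cell types (or a named vector
#'   over cell types).
#' @param markerEffect marker elevation factor (>= 1; 1 = no marker signal).
#' @param hybridFrac fraction of myonuclei simulated as hybrids.
#' @param fibreProps mixture of pure fibre types among non-hybrid myonuclei.
#' @param libsizeLognormal `(meanlog, sdlog)` of per-cell library size.
#' @param mitoFracBeta `(a, b)` of the per-cell mitochondrial fraction.
#' @param pseudotimeTrendGenes genes per trend archetype
#'   (`up`, `down`, `abrupt`, `flat`).
#' @param seed integer RNG seed.
#' @return A validated [SimConfig].
#' @examples
#' cfg <- simConfig(nSamplesPerGroup = 2, nCellsPerSample = 100, seed = 7)
#' cfg
#' @export
simConfig <- function(nSamplesPerGroup = 12L,
                      nCellsPerSample = 500L,
                      nGenes = 2000L,
                      cellTypeProps = c(
                        Myofibre = 0.45, MuSC = 0.05, FAP = 0.12, EC = 0.10,
                        SMC = 0.03, Pericyte = 0.04, Macrophage = 0.06,
                        Tcell = 0.03, Bcell = 0.02, NK = 0.02, Mast = 0.01,
                        Schwann = 0.02, Adipocyte = 0.02, Tenocyte = 0.02,
                        Erythrocyte = 0.01),
                      ageEffects = c(MuSC = -0.4, Macrophage = 0.3,
                                     Tcell = 0.3, FAP = 0.2,
                                     IIX = -0.5, IIA = -0.2),
                      dispersionAdult = 0.4,
                      dispersionOld = 0.8,
                      markerEffect = 4,
                      hybridFrac = 0.1,
                      fibreProps = c(I = 0.45, IIA = 0.35, IIX = 0.20),
                      libsizeLognormal = c(log(2500), 0.35),
                      mitoFracBeta = c(2, 80),
                      pseudotimeTrendGenes = c(up = 50L, down = 50L,
                                               abrupt = 25L, flat = 25L),
                      seed = 1L) {
  if (nSamplesPerGroup <= 0 || nCellsPerSample <= 0 || nGenes <= 0)
    stop("dimensions must be positive")
  types <- names(cellTypeProps)
  expand <- function(phi) {
    if (is.null(names(phi))) stats::setNames(rep_len(phi, length(types)), types)
    else phi[types]
  }
  disp <- cbind(adult = expand(dispersionAdult), old = expand(dispersionOld))
  rownames(disp) <- types
  new("SimConfig",
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      nCellsPerSample = as.integer(nCellsPerSample),
      nGenes = as.integer(nGenes),
      cellTypeProps = cellTypeProps,
      ageEffects = ageEffects,
      dispersion = disp,
      markerEffect = markerEffect,
      hybridFrac = hybridFrac,
      fibreProps = fibreProps[c("I", "IIA", "IIX")],
      libsizeLognormal = as.numeric(libsizeLognormal),
      mitoFracBeta = as.numeric(mitoFracBeta),
      pseudotimeTrendGenes = stats::setNames(
        as.integer(pseudotimeTrendGenes[c("up", "down", "abrupt", "flat")]),
        c("up", "down", "abrupt", "flat")),
      seed = as.integer(seed))
}

# Gene universe layout: mito block first, then the printed fibre-marker
# symbols, then per-cell-type marker blocks, then trend genes, then filler.
.geneUniverse <- function(config) {
  nGenes <- config@nGenes
  nMito <- ceiling(0.01 * nGenes)
  panels <- markerPanels()
  fibreGenes <- unique(unlist(lapply(panels, panelGenes), use.names = FALSE))
  types <- names(config@cellTypeProps)
  nTypeMarkers <- 10L
  nTrend <- sum(config@pseudotimeTrendGenes)
  nNeeded <- nMito + length(fibreGenes) + nTypeMarkers * length(types) + nTrend
  if (nGenes < nNeeded)
    stop("nGenes too small: need at least ", nNeeded,
         " for mito + marker + trend blocks")
  nFill <- nGenes - nMito - length(fibreGenes)
  genes <- c(paste0("MT-G", seq_len(nMito)), fibreGenes,
             sprintf("G%05d", seq_len(nFill)))
  pool <- genes[(nMito + length(fibreGenes) + 1L):nGenes]
  typeMarkers <- list()
  off <- 0L
  for (ct in types) {
    typeMarkers[[ct]] <- pool[off + seq_len(nTypeMarkers)]
    off <- off + nTypeMarkers
  }
  trendGenes <- list()
  for (arch in names(config@pseudotimeTrendGenes)) {
    n <- config@pseudotimeTrendGenes[[arch]]
    trendGenes[[arch]] <- if (n > 0L) pool[off + seq_len(n)] else character()
    off <- off + n
  }
  list(genes = genes, mito = genes[seq_len(nMito)],
       typeMarkers = typeMarkers, trendGenes = trendGenes, panels = panels)
}

# Mean-expression weight vector for one cell type (or fibre type within
# myonuclei). Hybrids average the two parent vectors.
.meanWeights <- function(universe, config, cellType, fibreType = NA_character_) {
  w <- universe$baseWeights
  w[universe$typeMarkers[[cellType]]] <- w[universe$typeMarkers[[cellType]]] *
    config@markerEffect
  if (!is.na(fibreType)) {
    p <- universe$panels
    elevate <- function(w, panel) {
      g <- panelGenes(p[[panel]])
      w[g] <- w[g] * config@markerEffect
      w
    }
    pure <- function(ft) {
      v <- w
      v <- switch(ft,
        "I" = elevate(v, "I"),
        "IIA" = elevate(elevate(v, "II"), "IIA"),
        "IIX" = elevate(elevate(v, "II"), "IIX"))
      v
    }
    w <- switch(fibreType,
      "I" = pure("I"),
      "IIA" = pure("IIA"),
      "IIX" = pure("IIX"),
      "hybrid I/IIA" = (pure("I") + pure("IIA")) / 2,
      "hybrid IIA/IIX" = (pure("IIA") + pure("IIX")) / 2)
  }
  w
}

# Pseudotime modulation factors for the trend archetypes; t in [0,1].
.trendFactor <- function(arch, t) {
  switch(arch,
    up = 1 + 2 * t,
    down = 3 - 2 * t,
    abrupt = 1 + 2 * stats::plogis((t - 0.8) / 0.04),
    flat = rep(1, length(t)))
}

.fibreMixture <- function(config, group) {
  pure <- config@fibreProps * (1 - config@hybridFrac)
  mix <- c(pure, "hybrid I/IIA" = config@hybridFrac / 2,
           "hybrid IIA/IIX" = config@hybridFrac / 2)
  if (group == "old") {
    hit <- intersect(names(config@ageEffects), names(mix))
    mix[hit] <- mix[hit] * exp(config@ageEffects[hit])
    mix <- mix / sum(mix)
  }
  mix
}

.sampleTable <- function(config) {
  nS <- config@nSamplesPerGroup
  ids <- c(sprintf("A%02d", seq_len(nS)), sprintf("O%02d", seq_len(nS)))
  n <- 2L * nS
  S4Vectors::DataFrame(
    sample_id = ids,
    age_years = as.integer(round(c(seq(20, 46, length.out = nS),
                                   seq(74, 99, length.out = nS)))),
    age_group = rep(c("adult", "old"), each = nS),
    sex = rep_len(c("M", "F"), n),
    ethnicity = rep_len(c("Spanish", "Spanish", "Chinese"), n),
    batch = rep_len(paste0("b", 1:4), n),
    modality = rep_len(c("snRNA", "scRNA"), n))
}

# Core simulator shared by generateAtlas() and generateGeneScores().
# value = "counts": negative-binomial integers; "scores": gamma-distributed
# nonnegative activities with the same mean/dispersion structure.
.simulateAtlas <- function(config, value = c("counts", "scores")) {
  value <- match.arg(value)
  validObject(config)
  set.seed(config@seed)
  universe <- .geneUniverse(config)
  genes <- universe$genes
  G <- length(genes)
  universe$baseWeights <- stats::setNames(stats::rlnorm(G, 0, 1), genes)
  isMito <- genes %in% universe$mito
  types <- names(config@cellTypeProps)
  samples <- .sampleTable(config)

  oldProps <- config@cellTypeProps
  hit <- intersect(names(config@ageEffects), types)
  oldProps[hit] <- oldProps[hit] * exp(config@ageEffects[hit])
  oldProps <- oldProps / sum(oldProps)

  # cache mean-weight vectors per (cell type [, fibre type])
  wCache <- list()
  getW <- function(ct, ft = NA_character_) {
    key <- paste(ct, ft, sep = "|")
    if (is.null(wCache[[key]]))
      wCache[[key]] <<- .meanWeights(universe, config, ct, ft)
    wCache[[key]]
  }

  blocks <- vector("list", nrow(samples))
  metaList <- vector("list", nrow(samples))
  ptBeta <- list(adult = c(1.5, 3), old = c(3, 1.5))

  for (s in seq_len(nrow(samples))) {
    grp <- samples$age_group[s]
    props <- if (grp == "old") oldProps else config@cellTypeProps
    nC <- config@nCellsPerSample
    ctCounts <- as.vector(stats::rmultinom(1L, nC, props))
    ct <- rep(types, ctCounts)
    ft <- rep(NA_character_, nC)
    pt <- rep(NA_real_, nC)
    isMyo <- ct == .MYO_LABEL
    if (any(isMyo)) {
      mix <- .fibreMixture(config, grp)
      ft[isMyo] <- sample(names(mix), sum(isMyo), replace = TRUE, prob = mix)
      pt[isMyo] <- stats::rbeta(sum(isMyo), ptBeta[[grp]][1], ptBeta[[grp]][2])
    }
    lib <- stats::rlnorm(nC, config@libsizeLognormal[1], config@libsizeLognormal[2])
    mito <- stats::rbeta(nC, config@mitoFracBeta[1], config@mitoFracBeta[2])
    phi <- stats::setNames(config@dispersion[, grp],
                           rownames(config@dispersion))

    # weight matrix: one column per cell, grouped by (cell type, fibre type)
    W <- matrix(0, nrow = G, ncol = nC, dimnames = list(genes, NULL))
    key <- paste(ct, ft, sep = "|")
    for (k in unique(key)) {
      cols <- key == k
      W[, cols] <- getW(ct[which(cols)[1L]], ft[which(cols)[1L]])
    }
    if (any(isMyo)) {
      for (arch in names(universe$trendGenes)) {
        g <- universe$trendGenes[[arch]]
        if (length(g))
          W[g, isMyo] <- W[g, isMyo] *
            rep(.trendFactor(arch, pt[isMyo]), each = length(g))
      }
    }
    # split per-cell expected mass between mito and non-mito genes
    sn <- colSums(W[!isMito, , drop = FALSE])
    sm <- colSums(W[isMito, , drop = FALSE])
    mu <- W
    mu[!isMito, ] <- t(t(W[!isMito, , drop = FALSE]) * (lib * (1 - mito) / sn))
    mu[isMito, ] <- t(t(W[isMito, , drop = FALSE]) * (lib * mito / sm))
    phiCell <- phi[ct]
    vals <- if (value == "counts") {
      x <- numeric(G * nC)
      muv <- as.vector(mu)
      phv <- rep(phiCell, each = G)
      pois <- phv == 0
      if (any(pois)) x[pois] <- stats::rpois(sum(pois), muv[pois])
      if (any(!pois)) x[!pois] <- stats::rnbinom(sum(!pois), mu = muv[!pois],
                                                 size = 1 / phv[!pois])
      x
    } else {
      muv <- as.vector(mu)
      phv <- rep(phiCell, each = G)
      x <- muv
      pos <- phv > 0 & muv > 0
      # Gamma with mean mu, variance phi * mu^2 (the NB mixing distribution)
      x[pos] <- stats::rgamma(sum(pos), shape = 1 / phv[pos],
                              scale = muv[pos] * phv[pos])
      x
    }
    m <- matrix(vals, nrow = G, ncol = nC)
    blocks[[s]] <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    metaList[[s]] <- S4Vectors::DataFrame(
      cell_id = sprintf("%s_c%04d", samples$sample_id[s], seq_len(nC)),
      sample_id = samples$sample_id[s],
      cell_type = ct,
      modality = samples$modality[s],
      fibre_type_true = ft,
      pseudotime_true = pt)
  }

  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metaList)
  rownames(counts) <- genes
  colnames(counts) <- meta$cell_id

  truth <- S4Vectors::DataFrame(
    cell_id = meta$cell_id,
    cell_type_true = meta$cell_type,
    fibre_type_true = meta$fibre_type_true,
    pseudotime_true = meta$pseudotime_true)

  adultN <- table(factor(meta$cell_type[meta$sample_id %in%
                           samples$sample_id[samples$age_group == "adult"]],
                         levels = types))
  oldN <- table(factor(meta$cell_type[meta$sample_id %in%
                         samples$sample_id[samples$age_group == "old"]],
                       levels = types))
  realizedFC <- log((oldN / sum(oldN)) / (adultN / sum(adultN)))

  cd <- meta[, c("cell_id", "sample_id", "cell_type", "modality")]
  rownames(cd) <- cd$cell_id
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = stats::setNames(list(counts), value),
    colData = cd)
  S4Vectors::metadata(sce) <- list(
    samples = samples,
    truth = truth,
    config = config,
    trendGenes = universe$trendGenes,
    realizedAbundanceLogFC = as.vector(realizedFC),
    dispersion = config@dispersion)
  names(S4Vectors::metadata(sce)$realizedAbundanceLogFC) <- types
  sce
}

#' Generate a synthetic multimodal muscle atlas
#'
#' Draws a sparse gene x cell count matrix plus cell/sample metadata and
#' ground-truth labels. Counts are negative binomial with gene-specific means:
#' cell-type and fibre-type marker genes are elevated `markerEffect`-fold in
#' their own type, hybrid myonuclei get the 50/50 mixture of their parent
#' fibre-type mean vectors, trend genes are modulated by the latent
#' degeneration pseudotime, and per-cell totals follow a lognormal library
#' size. Per-sample cell-type counts are multinomial, with the old group's
#' proportions tilted by `exp(ageEffects)`. Sex, ethnicity, batch and modality
#' are assigned round-robin across samples. Fully reproducible from the
#' config seed.
#'
#' @param config a [SimConfig], e.g. from [simConfig()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `"counts"` (sparse integers), `colData` columns `cell_id`, `sample_id`,
#'   `cell_type`, `modality`, and `metadata()` entries `samples` (sample
#'   table), `truth` (per-cell true cell type, fibre type, pseudotime),
#'   `config`, `trendGenes`, `realizedAbundanceLogFC` and `dispersion`.
#' @examples
#' sce <- generateAtlas(simConfig(nSamplesPerGroup = 1, nCellsPerSample = 50,
#'                                nGenes = 300, seed = 42))
#' dim(sce)
#' @seealso [generateGeneScores()], [writeFixture()], [readAtlas()]
#' @export
generateAtlas <- function(config) .simulateAtlas(config, "counts")

#' Generate a synthetic gene-activity score matrix
#'
#' Emulates the chromatin-accessibility arm: per-cell gene-activity scores
#' drawn from gamma distributions with the same group and dispersion structure
#' as [generateAtlas()] (mean \eqn{\mu}, variance \eqn{\phi\mu^2}). The
#' resulting nonnegative real matrix is intended to be rounded to integers by
#' [epigeneticNoisePerCell()].
#'
#' @inheritParams generateAtlas
#' @return A `SingleCellExperiment` with assay `"scores"` and the same
#'   metadata layout as [generateAtlas()].
#' @export
generateGeneScores <- function(config) .simulateAtlas(config, "scores")

#' Extract simulation ground truth / sample table from a synthetic atlas
#'
#' @param sce a `SingleCellExperiment` produced by [generateAtlas()] or read
#'   back by [readAtlas()].
#' @return `simTruth()`: the per-cell truth `DataFrame`; `sampleData()`: the
#'   sample-level covariate `DataFrame`.
#' @export
simTruth <- function(sce) S4Vectors::metadata(sce)$truth

#' @rdname simTruth
#' @export
sampleData <- function(sce) S4Vectors::metadata(sce)$samples
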