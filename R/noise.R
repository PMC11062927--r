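#' @include AllClasses.R io.R
NULL

#' Mann-Whitney U-test with exact enumeration
#'
#' Two-tailed Mann-Whitney U-test. The statistic is
#' \eqn{U = \sum_{i,j} [x_i > y_j] + \tfrac12 [x_i = y_j]}. For small samples
#' (`n + m <= 12` under `mode = "auto"`, or `mode = "exact"`) the two-sided p
#' value is computed by full enumeration of all `choose(n + m, n)` group
#' assignments of the pooled values (midranks handle ties exactly); otherwise
#' a normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_tie_corrected"`.
#' @return A list with `U`, `p` (two-sided) and `method`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4), mode = "exact")  # U = 0, p = 1/3
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "normal_tie_corrected")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  N <- n + m
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "normal_tie_corrected"
  if (mode == "exact") {
    combos <- utils::combn(N, n)
    Us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
  } else {
    ties <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - n * m / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p = p, method = mode)
}

#' Select expression-invariant genes
#'
#' Ranks expressed genes (mean > 0) by average normalized expression, splits
#' the ranking into `nBlocks` near-equal blocks, and selects within each block
#' the fraction `lowestFrac` of genes with the smallest coefficient of
#' variation (sd/mean). Block sizes differ by at most one; the remainder goes
#' to the highest-expression blocks. Ties (in mean or CV) are broken by gene
#' id for determinism.
#'
#' @param nm normalized expression matrix (genes x cells), e.g. from
#'   [normalizeLog1p()], or a `SingleCellExperiment` with `"logcounts"`.
#' @param nBlocks number of expression blocks (default 10).
#' @param lowestFrac fraction of lowest-CV genes kept per block (default 0.1);
#'   `ceiling(lowestFrac * block_size)` genes are kept.
#' @return A `DataFrame` of the selected genes with columns `gene`, `mean`,
#'   `cv`, `block`.
#' @export
selectInvariantGenes <- function(nm, nBlocks = 10L, lowestFrac = 0.1) {
  stopifnot(nBlocks >= 1L, lowestFrac > 0, lowestFrac <= 1)
  if (methods::is(nm, "SummarizedExperiment"))
    nm <- SummarizedExperiment::assay(nm, "logcounts")
  mu <- Matrix::rowMeans(nm)
  keep <- mu > 0
  if (sum(keep) < nBlocks)
    stop("fewer expressed genes (", sum(keep), ") than blocks (", nBlocks, ")")
  nm <- nm[keep, , drop = FALSE]
  mu <- mu[keep]
  nc <- ncol(nm)
  ex2 <- Matrix::rowMeans(nm^2)
  v <- pmax(ex2 - mu^2, 0) * nc / max(nc - 1, 1)
  cv <- sqrt(v) / mu
  ord <- order(mu, rownames(nm))
  G <- length(ord)
  base <- G %/% nBlocks
  extra <- G %% nBlocks
  sizes <- rep(base, nBlocks)
  if (extra > 0)  # remainder to the highest-expression blocks
    sizes[(nBlocks - extra + 1L):nBlocks] <- base + 1L
  block <- rep(seq_len(nBlocks), sizes)
  sel <- integer()
  for (b in seq_len(nBlocks)) {
    idx <- ord[block == b]
    nSel <- ceiling(lowestFrac * length(idx))
    idx <- idx[order(cv[idx], rownames(nm)[idx])]
    sel <- c(sel, idx[seq_len(nSel)])
  }
  blockOf <- integer(G)
  blockOf[ord] <- block
  S4Vectors::DataFrame(gene = rownames(nm)[sel], mean = unname(mu[sel]),
                       cv = unname(cv[sel]), block = blockOf[sel])
}

# Shared matched-downsampling noise pipeline on a raw count matrix with a
# two-level group vector. Returns the NoiseResult pieces.
.noisePipeline <- function(m, groups, cellType, nMax, seed, nBlocks,
                           lowestFrac, targetSum, method) {
  groups <- as.character(groups)
  lev <- c("adult", "old")
  if (!all(lev %in% groups))
    stop("both age groups must be present for cell type '", cellType, "'")
  ids <- colnames(m)
  # Seeds and processing order follow the physical cell sets (by smallest
  # cell id), not the labels, so relabeling the two groups leaves every
  # random choice -- and hence every distance -- unchanged.
  sets <- list(ids[groups == lev[1]], ids[groups == lev[2]])
  ord <- order(vapply(sets, min, character(1)))
  keep <- vector("list", 2L)
  for (k in 1:2)
    keep[[ord[k]]] <- downsampleCells(sets[[ord[k]]], nMax, seed = seed + k)
  nCommon <- min(lengths(keep))
  for (k in 1:2)
    keep[[ord[k]]] <- downsampleCells(keep[[ord[k]]], nCommon,
                                      seed = seed + 2L + k)
  cells <- sort(c(keep[[1]], keep[[2]]))
  sub <- m[, cells, drop = FALSE]
  grp <- ifelse(cells %in% keep[[1]], lev[1], lev[2])
  target <- min(Matrix::colSums(sub))
  if (target == 0) stop("common target total is 0; remove empty cells first")
  sub <- downsampleCounts(sub, target, seed = seed + 5L)
  nmat <- .normalizeMatrix(sub, targetSum)
  inv <- selectInvariantGenes(nmat, nBlocks, lowestFrac)
  sm <- as.matrix(nmat[inv$gene, , drop = FALSE])
  dist <- numeric(ncol(sm))
  for (g in lev) {
    cols <- grp == g
    xg <- sm[, cols, drop = FALSE]
    if (method == "centroid") {
      centroid <- rowMeans(xg)
      dist[cols] <- sqrt(colSums((xg - centroid)^2))
    } else {  # mean pairwise distance within the group
      d2 <- as.matrix(stats::dist(t(xg)))
      dist[cols] <- rowSums(d2) / max(ncol(xg) - 1, 1)
    }
  }
  mw <- mannWhitneyU(dist[grp == "adult"], dist[grp == "old"])
  list(
    distances = S4Vectors::DataFrame(cell_id = colnames(sm), group = grp,
                                     distance = dist),
    summary = S4Vectors::DataFrame(
      cell_type = cellType,
      median_adult = stats::median(dist[grp == "adult"]),
      median_old = stats::median(dist[grp == "old"]),
      U = mw$U, p = mw$p),
    invariantGenes = inv$gene)
}

.groupsForCells <- function(sce, cells) {
  samples <- S4Vectors::metadata(sce)$samples
  if (is.null(samples) || !"age_group" %in% colnames(samples))
    stop("metadata(sce)$samples with an age_group column is required")
  cd <- SummarizedExperiment::colData(sce)
  grp <- samples$age_group[match(cd$sample_id[match(cells, cd$cell_id)],
                                 samples$sample_id)]
  if (anyNA(grp)) stop("cells with unknown sample or age group")
  grp
}

#' Per-cell transcriptional heterogeneity after matched downsampling
#'
#' The transcriptional "noise" statistic for one cell type: (i) each age
#' group is downsampled to at most `nMax` cells (cell types with fewer cells
#' keep them all); (ii) cell numbers are equalized across groups; (iii) every
#' retained cell is downsampled to the common minimum total count so depth is
#' identical everywhere; (iv) counts are log-normalized; (v) invariant genes
#' are selected (10 expression blocks, lowest-CV 10\% per block, jointly over
#' both groups); (vi) each cell's heterogeneity is its Euclidean distance over
#' the invariant genes to the centroid of its own (cell type x age group)
#' population. Group medians are compared with a two-tailed Mann-Whitney
#' U-test. Fully reproducible from `seed`.
#'
#' @param sce `SingleCellExperiment` with a counts assay, `colData` columns
#'   `cell_id`, `sample_id`, `cell_type`, and a sample table with `age_group`
#'   in `metadata(sce)$samples`.
#' @param cellType the cell type to analyse.
#' @param nMax per-group cell cap before matching (default 300).
#' @param seed integer seed driving every downsampling step.
#' @param nBlocks,lowestFrac invariant-gene selection parameters.
#' @param targetSum normalization target (default 10,000).
#' @param method `"centroid"` (distance to own-group centroid, default) or
#'   `"pairwise"` (mean distance to the other cells of the group).
#' @return A [NoiseResult].
#' @seealso [epigeneticNoisePerCell()], [selectInvariantGenes()],
#'   [mannWhitneyU()]
#' @export
noisePerCell <- function(sce, cellType, nMax = 300L, seed = 1L,
                         nBlocks = 10L, lowestFrac = 0.1, targetSum = 1e4,
                         method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  cd <- SummarizedExperiment::colData(sce)
  cells <- cd$cell_id[cd$cell_type == cellType]
  if (!length(cells)) stop("no cells of type '", cellType, "'")
  m <- .countsAssay(sce)[, cells, drop = FALSE]
  grp <- .groupsForCells(sce, cells)
  parts <- .noisePipeline(m, grp, cellType, nMax, seed, nBlocks, lowestFrac,
                          targetSum, method)
  new("NoiseResult", distances = parts$distances, summary = parts$summary,
      cellType = cellType, invariantGenes = parts$invariantGenes,
      seed = as.integer(seed))
}

# Round half away from zero (locale-independent, unlike round()).
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-cell epigenetic heterogeneity from gene-activity scores
#'
#' The epigenetic twin of [noisePerCell()]: the real-valued gene-activity
#' score matrix is first rounded to integers (half away from zero), then the
#' identical matched-downsampling noise pipeline is applied verbatim.
#'
#' @param gs `SingleCellExperiment` with a `"scores"` assay (e.g. from
#'   [generateGeneScores()]), or a nonnegative real matrix.
#' @inheritParams noisePerCell
#' @return A [NoiseResult].
#' @export
epigeneticNoisePerCell <- function(gs, cellType, nMax = 300L, seed = 1L,
                                   nBlocks = 10L, lowestFrac = 0.1,
                                   targetSum = 1e4,
                                   method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  m <- .countsAssay(gs)
  m <- methods::as(m, "CsparseMatrix")
  m@x <- .roundHalfAway(m@x)
  m <- Matrix::drop0(m)
  cd <- SummarizedExperiment::colData(gs)
  cells <- cd$cell_id[cd$cell_type == cellType]
  if (!length(cells)) stop("no cells of type '", cellType, "'")
  grp <- .groupsForCells(gs, cells)
  parts <- .noisePipeline(m[, cells, drop = FALSE], grp, cellType, nMax, seed,
                          nBlocks, lowestFrac, targetSum, method)
  new("NoiseResult", distances = parts$distances, summary = parts$summary,
      cellType = cellType, invariantGenes = parts$invariantGenes,
      seed = as.integer(seed))
}
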