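#' @include AllClasses.R fibre.R
NULL

#' Assign cells to equal-count pseudotime bins
#'
#' Cells are ranked by pseudotime (ties broken by cell id for a total order)
#' and split into `nBins` equal-count bins whose sizes differ by at most one.
#' The mapping is monotone: a larger pseudotime never gets a smaller bin
#' index, so any strictly monotone transform of the pseudotime yields the
#' same binning.
#'
#' @param pseudotime named numeric vector of finite pseudotimes (names = cell
#'   ids; unnamed vectors are ordered by position).
#' @param nBins number of bins (default 100); requires
#'   `length(pseudotime) >= nBins`.
#' @return Integer vector of bin indices in `[1, nBins]`, aligned with (and
#'   named like) the input.
#' @examples
#' binPseudotime(c(a = 0.1, b = 0.9, c = 0.5, d = 0.2), nBins = 2)
#' @export
binPseudotime <- function(pseudotime, nBins = 100L) {
  if (anyNA(pseudotime) || any(!is.finite(pseudotime)))
    stop("pseudotime must be finite and non-missing")
  n <- length(pseudotime)
  stopifnot(nBins >= 1L, n >= nBins)
  ids <- if (is.null(names(pseudotime))) as.character(seq_len(n))
         else names(pseudotime)
  ord <- order(pseudotime, ids)
  bin <- integer(n)
  bin[ord] <- as.integer(ceiling(seq_len(n) * nBins / n))
  names(bin) <- names(pseudotime)
  bin
}

#' Aggregate expression into pseudotime bins
#'
#' @param nm normalized matrix (genes x cells) or `SingleCellExperiment` with
#'   `"logcounts"`; columns must match the binned cells.
#' @param bins integer bin index per cell (from [binPseudotime()]).
#' @return A bins x genes matrix of mean normalized expression per bin.
#' @export
aggregateBins <- function(nm, bins) {
  nm <- .logcountsOf(nm)
  if (length(bins) != ncol(nm))
    stop("bins must cover every cell (one index per column)")
  nBins <- max(bins)
  sizes <- tabulate(bins, nBins)
  if (any(sizes == 0)) stop("empty bin encountered")
  ind <- Matrix::sparseMatrix(i = seq_along(bins), j = bins,
                              x = 1 / sizes[bins],
                              dims = c(length(bins), nBins))
  out <- t(as.matrix(nm %*% ind))
  rownames(out) <- seq_len(nBins)
  colnames(out) <- rownames(nm)
  out
}

#' Select the most variable binned gene trends
#'
#' Genes ranked by the variance of their binned trend, descending; ties
#' broken by gene id.
#'
#' @param binMat bins x genes matrix from [aggregateBins()].
#' @param nTop number of genes to return (`<=` number of genes).
#' @return Character vector of the top `nTop` gene ids.
#' @export
selectVariableGenes <- function(binMat, nTop = 4000L) {
  stopifnot(nTop <= ncol(binMat))
  v <- apply(binMat, 2L, stats::var)
  colnames(binMat)[order(-v, colnames(binMat))][seq_len(nTop)]
}

# k-means++ seeding: first center uniform, then prob proportional to the
# squared distance to the nearest chosen center.
.kmeansPlusPlus <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - rep(x[centers[1L], ], each = n))^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((x - rep(x[centers[j + 1L], ], each = n))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster gene trends along the trajectory
#'
#' k-means on the z-scored (per gene, across bins) trend matrix, with
#' k-means++ initialization and `nInit` restarts; the restart with the lowest
#' total within-cluster sum of squares is kept. Clusters are relabeled in
#' order of the bin index at which their centroid peaks, so cluster 1 always
#' peaks earliest. Deterministic given `seed`.
#'
#' @param binMat bins x genes matrix from [aggregateBins()].
#' @param genes gene ids to cluster (e.g. from [selectVariableGenes()]).
#' @param k number of clusters (default 10; must be `<= length(genes)`).
#' @param seed integer seed.
#' @param nInit number of k-means++ restarts (default 10).
#' @return A [TrendClusters].
#' @export
clusterGeneTrends <- function(binMat, genes, k = 10L, seed = 1L,
                              nInit = 10L) {
  if (k > length(genes)) stop("k exceeds the number of genes")
  x <- t(binMat[, genes, drop = FALSE])   # genes x bins
  x <- t(apply(x, 1L, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  best <- NULL
  .withSeed(seed, {
    for (i in seq_len(nInit)) {
      centers <- .kmeansPlusPlus(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  peak <- apply(best$centers, 1L, which.max)
  ord <- order(peak, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  new("TrendClusters",
      genes = genes,
      cluster = as.integer(relabel[best$cluster]),
      centroids = best$centers[ord, , drop = FALSE],
      inertia = best$tot.withinss)
}

#' Age-group occupancy per pseudotime bin
#'
#' @param bins integer bin index per cell (from [binPseudotime()]).
#' @param groups character age-group label per cell (`"adult"` / `"old"`),
#'   aligned with `bins`.
#' @return A `DataFrame` with columns `bin`, `prop_adult`, `prop_old`
#'   (summing to 1 per bin).
#' @export
groupProportionPerBin <- function(bins, groups) {
  if (length(bins) != length(groups)) stop("bins and groups must align")
  if (anyNA(groups)) stop("every cell needs a group label")
  nBins <- max(bins)
  tab <- table(factor(bins, levels = seq_len(nBins)),
               factor(groups, levels = c("adult", "old")))
  prop <- tab / pmax(rowSums(tab), 1)
  S4Vectors::DataFrame(bin = seq_len(nBins),
                       prop_adult = as.numeric(prop[, "adult"]),
                       prop_old = as.numeric(prop[, "old"]))
}

#' Average module score along the trajectory
#'
#' Per-cell [moduleScore()] of a panel, averaged within each pseudotime bin.
#' The bin mean equals the mean of the per-cell scores exactly.
#'
#' @param nm normalized matrix or `SingleCellExperiment` with `"logcounts"`.
#' @param bins integer bin index per cell.
#' @param panel a [MarkerPanel] or character gene set.
#' @inheritParams moduleScore
#' @return Numeric vector of per-bin mean scores (length `max(bins)`).
#' @export
panelScoreAlongTrajectory <- function(nm, bins, panel, nBins = 25L,
                                      nCtrl = 100L, seed = 1L) {
  sc <- moduleScore(nm, panel, nBins = nBins, nCtrl = nCtrl, seed = seed)
  as.numeric(tapply(sc, factor(bins, levels = seq_len(max(bins))), mean))
}
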