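#' @include AllClasses.R
NULL

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.countsAssay <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L)
  else x
}

#' Write a synthetic atlas fixture to disk
#'
#' Emits the on-disk exchange format consumed by [readAtlas()]:
#' `matrix.mtx` (MatrixMarket coordinate triplets), `genes.tsv`, `cells.tsv`,
#' `samples.tsv`, `truth.tsv` and `manifest.json` (seed and configuration
#' echo). Writing then reading back reproduces the sparse matrix exactly, and
#' two runs from the same seed produce byte-identical files.
#'
#' @param sce a `SingleCellExperiment` from [generateAtlas()] /
#'   [generateGeneScores()] (or [readAtlas()]).
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
writeFixture <- function(sce, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  m <- .countsAssay(sce)
  cd <- SummarizedExperiment::colData(sce)
  if (!identical(colnames(m), as.character(cd$cell_id)))
    stop("id mismatch between matrix columns and cell metadata")
  truth <- S4Vectors::metadata(sce)$truth
  if (!is.null(truth)) {
    if (!all(cd$cell_id %in% truth$cell_id))
      stop("id mismatch between truth table and cell metadata")
    truth <- truth[match(cd$cell_id, truth$cell_id), , drop = FALSE]
  }

  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  tsv <- function(df, file) {
    utils::write.table(as.data.frame(df), file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(data.frame(gene_id = rownames(m)), "genes.tsv")
  tsv(cd[, c("cell_id", "sample_id", "cell_type", "modality")], "cells.tsv")
  samples <- S4Vectors::metadata(sce)$samples
  if (!is.null(samples)) tsv(samples, "samples.tsv")
  if (!is.null(truth)) {
    tt <- as.data.frame(truth)
    tt$pseudotime_true <- ifelse(is.na(tt$pseudotime_true), NA,
                                 sprintf("%.17g", tt$pseudotime_true))
    tsv(tt, "truth.tsv")
  }
  config <- S4Vectors::metadata(sce)$config
  manifest <- list(
    format = "agemyo-fixture-1",
    seed = if (!is.null(config)) config@seed else NA_integer_,
    n_genes = nrow(m), n_cells = ncol(m),
    nnz = Matrix::nnzero(m),
    assay = SummarizedExperiment::assayNames(sce)[1L],
    files = c("matrix.mtx", "genes.tsv", "cells.tsv", "samples.tsv",
              "truth.tsv"),
    config = if (!is.null(config)) {
      list(nSamplesPerGroup = config@nSamplesPerGroup,
           nCellsPerSample = config@nCellsPerSample,
           nGenes = config@nGenes,
           cellTypeProps = as.list(config@cellTypeProps),
           ageEffects = as.list(config@ageEffects),
           dispersionAdult = as.list(config@dispersion[, "adult"]),
           dispersionOld = as.list(config@dispersion[, "old"]),
           markerEffect = config@markerEffect,
           hybridFrac = config@hybridFrac,
           seed = config@seed)
    })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read an atlas fixture from disk
#'
#' Reads the `matrix.mtx` + TSV sidecar layout written by [writeFixture()]
#' back into a `SingleCellExperiment`, checking that the MatrixMarket header
#' dimensions agree with the sidecar lengths and that count values are
#' nonnegative integers.
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv` and
#'   optionally `samples.tsv`, `truth.tsv`, `manifest.json`.
#' @param assayName name for the assay (`"counts"` enforces integer values;
#'   use `"scores"` for real-valued gene-activity fixtures).
#' @return A `SingleCellExperiment`.
#' @export
readAtlas <- function(dir, assayName = "counts") {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  if (methods::is(m, "nMatrix"))   # pattern matrix (e.g. no stored entries)
    m <- methods::as(m, "dMatrix")
  m <- methods::as(m, "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "genes.tsv"), header = TRUE,
                             sep = "\t", colClasses = "character")
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                             sep = "\t", colClasses = "character")
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
    stop("dimension mismatch between matrix.mtx header and TSV sidecars")
  if (anyDuplicated(genes$gene_id) || anyDuplicated(cells$cell_id))
    stop("gene or cell ids are not unique")
  if (length(m@x)) {
    if (any(m@x < 0)) stop("negative values in count matrix")
    if (assayName == "counts" && any(m@x %% 1 != 0))
      stop("non-integer values in count matrix")
  }
  rownames(m) <- genes$gene_id
  colnames(m) <- cells$cell_id
  cd <- S4Vectors::DataFrame(cells, row.names = cells$cell_id)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = stats::setNames(list(m), assayName), colData = cd)
  meta <- list()
  sfile <- file.path(dir, "samples.tsv")
  if (file.exists(sfile))
    meta$samples <- S4Vectors::DataFrame(
      utils::read.table(sfile, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE))
  tfile <- file.path(dir, "truth.tsv")
  if (file.exists(tfile)) {
    tt <- utils::read.table(tfile, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if ("pseudotime_true" %in% colnames(tt))
      tt$pseudotime_true <- as.numeric(tt$pseudotime_true)
    meta$truth <- S4Vectors::DataFrame(tt)
  }
  mfile <- file.path(dir, "manifest.json")
  if (file.exists(mfile)) meta$manifest <- jsonlite::read_json(mfile)
  S4Vectors::metadata(sce) <- meta
  sce
}

#' Quality-control filter for cells
#'
#' Retains exactly the cells with total counts strictly greater than
#' `minUMI`, strictly more than `minGenes` detected genes (count > 0), and a
#' mitochondrial fraction strictly below `maxMitoFrac`. The bounds are strict
#' inequalities, so a cell sitting exactly on a threshold is removed. The
#' gene list is unchanged.
#'
#' @param sce a `SingleCellExperiment` with a counts assay (or a sparse
#'   matrix).
#' @param minUMI exclusive lower bound on per-cell total counts.
#' @param minGenes exclusive lower bound on detected genes.
#' @param maxMitoFrac exclusive upper bound on the mitochondrial count
#'   fraction, in `[0, 1]`.
#' @param mitoPrefix gene-id prefix identifying mitochondrial genes.
#' @return The filtered object, with a QC report in
#'   `metadata(.)$qc` (or `attr(., "qc")` for a matrix input): cells before /
#'   after and per-criterion removal counts.
#' @examples
#' sce <- generateAtlas(simConfig(nSamplesPerGroup = 1, nCellsPerSample = 80,
#'                                nGenes = 300, seed = 3))
#' filtered <- qcFilter(sce, minUMI = 1000, minGenes = 100, maxMitoFrac = 0.05)
#' S4Vectors::metadata(filtered)$qc
#' @export
qcFilter <- function(sce, minUMI = 1000, minGenes = 500, maxMitoFrac = 0.05,
                     mitoPrefix = "MT-") {
  stopifnot(minUMI >= 0, minGenes >= 0,
            maxMitoFrac >= 0, maxMitoFrac <= 1)
  m <- .countsAssay(sce)
  totals <- Matrix::colSums(m)
  detected <- Matrix::colSums(m > 0)
  isMito <- startsWith(rownames(m), mitoPrefix)
  mitoFrac <- if (any(isMito)) {
    Matrix::colSums(m[isMito, , drop = FALSE]) / pmax(totals, 1)
  } else rep(0, ncol(m))
  passUMI <- totals > minUMI
  passGenes <- detected > minGenes
  passMito <- mitoFrac < maxMitoFrac
  keep <- passUMI & passGenes & passMito
  report <- list(
    n_before = ncol(m), n_after = sum(keep),
    removed_low_umi = sum(!passUMI),
    removed_low_genes = sum(!passGenes),
    removed_high_mito = sum(!passMito),
    thresholds = c(min_umi = minUMI, min_genes = minGenes,
                   max_mito_frac = maxMitoFrac))
  if (!any(keep)) warning("no cells pass QC")
  if (methods::is(sce, "SummarizedExperiment")) {
    out <- sce[, keep]
    S4Vectors::metadata(out)$qc <- report
  } else {
    out <- m[, keep, drop = FALSE]
    attr(out, "qc") <- report
  }
  out
}

# Column-scale a sparse count matrix to targetSum and log1p-transform.
.normalizeMatrix <- function(m, targetSum = 1e4) {
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) stop("zero-total cell: run qcFilter first")
  out <- methods::as(m, "CsparseMatrix")
  scale <- targetSum / totals
  if (length(out@x))
    out@x <- log1p(out@x * rep.int(scale, diff(out@p)))
  out
}

#' Total-count normalization and log transform
#'
#' Scales each cell to `targetSum` total counts and applies `log1p`:
#' `value = ln(1 + count * targetSum / cell_total)`. Zero counts stay zero and
#' the transform is monotone within a cell.
#'
#' @param sce a `SingleCellExperiment` with counts (or a sparse matrix).
#' @param targetSum target per-cell total after scaling (default 10,000).
#' @return For a `SingleCellExperiment`, the object with a `"logcounts"`
#'   assay added; for a matrix, the normalized sparse matrix.
#' @export
normalizeLog1p <- function(sce, targetSum = 1e4) {
  if (methods::is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logcounts") <-
      .normalizeMatrix(.countsAssay(sce), targetSum)
    sce
  } else {
    .normalizeMatrix(sce, targetSum)
  }
}

#' Downsample a cell-id set to a maximum size
#'
#' Simple random sample without replacement of size `min(nMax, length(ids))`;
#' if the set already fits, it is returned unchanged (all cells kept, as for
#' cell types with fewer cells than the cap). Deterministic given `seed`.
#'
#' @param cellIds character vector of cell ids.
#' @param nMax maximum number of cells to keep (> 0).
#' @param seed integer seed.
#' @return A character vector of retained ids (original order preserved).
#' @export
downsampleCells <- function(cellIds, nMax, seed = 1L) {
  stopifnot(nMax > 0)
  if (length(cellIds) <= nMax) return(cellIds)
  keep <- .withSeed(seed, sort.int(sample.int(length(cellIds), nMax)))
  cellIds[keep]
}

# Multivariate-hypergeometric draw of n items from count vector k (sum N):
# sample n of the N individual molecules without replacement and re-tabulate.
.mvhyper <- function(k, n) {
  N <- sum(k)
  if (n == N) return(k)
  pos <- sort.int(sample.int(N, n))
  cum <- cumsum(k)
  idx <- findInterval(pos - 0.5, cum) + 1L
  tabulate(idx, nbins = length(k))
}

#' Downsample counts to an exact per-cell total
#'
#' Replaces each cell's count vector by a multivariate-hypergeometric draw of
#' exactly `targetTotal` molecules without replacement from its observed
#' counts. Every cell's total therefore equals `targetTotal` exactly, no
#' entry exceeds its original value, and zeros stay zero. This is the
#' depth-matching primitive used to equalize UMI counts between age groups.
#'
#' @param m sparse count matrix (genes x cells) or `SingleCellExperiment`.
#' @param targetTotal target total per cell; must not exceed any included
#'   cell's total.
#' @param seed integer seed.
#' @return An object of the same class with downsampled counts.
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(8, 2),
#'                           dims = c(2, 1))
#' Matrix::colSums(downsampleCounts(m, 5, seed = 1))
#' @export
downsampleCounts <- function(m, targetTotal, seed = 1L) {
  isSE <- methods::is(m, "SummarizedExperiment")
  mat <- .countsAssay(m)
  mat <- methods::as(mat, "CsparseMatrix")
  totals <- Matrix::colSums(mat)
  if (any(totals < targetTotal))
    stop("targetTotal exceeds the total of ", sum(totals < targetTotal),
         " cell(s)")
  .withSeed(seed, {
    xs <- mat@x
    for (j in seq_len(ncol(mat))) {
      lo <- mat@p[j] + 1L
      hi <- mat@p[j + 1L]
      if (hi < lo) next
      xs[lo:hi] <- .mvhyper(mat@x[lo:hi], targetTotal)
    }
    mat@x <- xs
  })
  mat <- Matrix::drop0(mat)
  if (isSE) {
    SummarizedExperiment::assay(m, 1L) <- mat
    m
  } else mat
}
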