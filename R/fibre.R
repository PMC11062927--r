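#' @include AllClasses.R io.R noise.R
NULL

#' Myofibre-type marker panels
#'
#' The four marker panels used for myonucleus classification: pan type I
#' (slow/oxidative, MYH7 program), pan type II (fast, TNNT3 program), and the
#' type IIA and type IIX subtype panels. Genes are HGNC symbols.
#'
#' @return A named list of [MarkerPanel] objects (`I`, `II`, `IIA`, `IIX`).
#' @examples
#' markerPanels()$I
#' @export
markerPanels <- function() {
  mk <- function(name, genes) new("MarkerPanel", name = name, genes = genes)
  list(
    I = mk("I", c("TNNT1", "MYH7", "MYH7B", "TNNC1", "TNNI1", "ATP2A2")),
    II = mk("II", c("TNNT3", "MYH1", "MYH2", "TNNC2", "TNNI2", "ATP2A1")),
    IIA = mk("IIA", c("MYH2", "ANKRD2", "NDUFA8", "MYOM3", "CASQ2", "HSPB6",
                      "RDH11", "AIMP1")),
    IIX = mk("IIX", c("MYH1", "MYLK2", "ACTN3", "MYBPC2", "PCYOX1", "CAPZA1",
                      "CD38", "PDLIM7", "COBL", "TMEM159", "HNRNPA1", "TFRC"))
  )
}

#' Read marker panels from a YAML or JSON file
#'
#' Expects a mapping `{panel_name: [gene, ...]}`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of [MarkerPanel] objects.
#' @export
readMarkerPanels <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(names(raw), function(nm)
    new("MarkerPanel", name = nm, genes = as.character(unlist(raw[[nm]]))))
  stats::setNames(out, names(raw))
}

.logcountsOf <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
      stop("run normalizeLog1p() first: no 'logcounts' assay")
    SummarizedExperiment::assay(x, "logcounts")
  } else x
}

#' Module score of a gene panel per cell
#'
#' The classic expression-matched control scheme: all genes are split into
#' `nBins` equal-count bins of average expression; for each panel gene,
#' `nCtrl` control genes are sampled from its bin (panel genes are excluded
#' from the control pool; without replacement when the bin is large enough,
#' with replacement otherwise). The score of a cell
#' is the mean normalized expression of the panel genes minus the mean over
#' the pooled control draw. Deterministic given `seed`. Panel genes missing
#' from the matrix are dropped with a warning; an entirely absent panel is an
#' error.
#'
#' @param nm normalized matrix (genes x cells) or `SingleCellExperiment` with
#'   `"logcounts"`.
#' @param panel a [MarkerPanel] or character vector of gene ids.
#' @param nBins number of average-expression bins (default 25).
#' @param nCtrl control genes sampled per panel gene (default 100).
#' @param seed integer seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
moduleScore <- function(nm, panel, nBins = 25L, nCtrl = 100L, seed = 1L) {
  nm <- .logcountsOf(nm)
  genes <- if (methods::is(panel, "MarkerPanel")) panelGenes(panel)
           else as.character(panel)
  present <- intersect(genes, rownames(nm))
  if (!length(present))
    stop("no panel gene is present in the matrix")
  if (length(present) < length(genes))
    warning("dropping ", length(genes) - length(present),
            " panel gene(s) absent from the matrix")
  mu <- Matrix::rowMeans(nm)
  ord <- order(mu, rownames(nm))
  G <- length(mu)
  bin <- integer(G)
  bin[ord] <- ceiling(seq_len(G) * nBins / G)
  panelIdx <- match(present, rownames(nm))
  ctrlIdx <- .withSeed(seed, {
    unlist(lapply(panelIdx, function(i) {
      mates <- setdiff(which(bin == bin[i]), panelIdx)
      if (!length(mates)) mates <- which(bin == bin[i])
      if (length(mates) >= nCtrl) sample(mates, nCtrl)
      else sample(mates, nCtrl, replace = TRUE)
    }), use.names = FALSE)
  })
  panelMean <- Matrix::colMeans(nm[panelIdx, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(nm[ctrlIdx, , drop = FALSE])
  stats::setNames(as.numeric(panelMean - ctrlMean), colnames(nm))
}

#' Module scores for the four fibre-type panels
#'
#' Convenience wrapper computing [moduleScore()] for each of the `I`, `II`,
#' `IIA` and `IIX` panels on the same matrix.
#'
#' @inheritParams moduleScore
#' @param panels named list of panels (default [markerPanels()]).
#' @return A cells x panels numeric matrix.
#' @export
fibreModuleScores <- function(nm, panels = markerPanels(), nBins = 25L,
                              nCtrl = 100L, seed = 1L) {
  out <- vapply(seq_along(panels), function(i)
    moduleScore(nm, panels[[i]], nBins = nBins, nCtrl = nCtrl,
                seed = seed + i),
    numeric(ncol(.logcountsOf(nm))))
  colnames(out) <- names(panels)
  rownames(out) <- colnames(.logcountsOf(nm))
  out
}

#' Hierarchical myofibre-type classification of myonuclei
#'
#' Two-tier decision rule on z-standardized module scores. Tier 1 uses the
#' pan type I and pan type II scores: a nucleus is `unclassified` when
#' `max(z_I, z_II) < tau`; called `hybrid I/IIA` when both `z_I` and `z_IIA`
#' reach `tau` and differ by less than `delta` (the hybrid test precedes the
#' argmax, otherwise hybrids would be unreachable); otherwise the larger of
#' `z_I` / `z_II` wins. Tier 2 subdivides type II nuclei the same way using
#' the IIA and IIX scores (`hybrid IIA/IIX`). Ties in the argmax go to the
#' more oxidative class (I at tier 1, IIA at tier 2). Tier 2 is `"n/a"` for
#' nuclei not called type II.
#'
#' @param scores cells x panels matrix with columns `I`, `II`, `IIA`, `IIX`
#'   (e.g. from [fibreModuleScores()]); scores are z-standardized across
#'   cells per panel before thresholding.
#' @param tau z-score floor below which a nucleus is unclassified
#'   (default 0).
#' @param delta maximum z-score gap for a hybrid call (default 0.5).
#' @return A `DataFrame` with columns `cell_id`, `tier1`, `tier2`,
#'   `final_class`.
#' @export
classifyFibreTypes <- function(scores, tau = 0, delta = 0.5) {
  need <- c("I", "II", "IIA", "IIX")
  if (!all(need %in% colnames(scores)))
    stop("scores must contain panels: ", paste(need, collapse = ", "))
  z <- apply(scores[, need, drop = FALSE], 2L, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  n <- nrow(z)
  tier1 <- character(n)
  unc1 <- pmax(z[, "I"], z[, "II"]) < tau
  hyb1 <- !unc1 & pmin(z[, "I"], z[, "IIA"]) >= tau &
    abs(z[, "I"] - z[, "IIA"]) < delta
  tier1[unc1] <- "unclassified"
  tier1[hyb1] <- "hybrid I/IIA"
  rest <- !unc1 & !hyb1
  tier1[rest] <- ifelse(z[rest, "I"] >= z[rest, "II"], "type I", "type II")

  tier2 <- rep("n/a", n)
  t2 <- tier1 == "type II"
  if (any(t2)) {
    zA <- z[t2, "IIA"]
    zX <- z[t2, "IIX"]
    sub <- character(sum(t2))
    unc2 <- pmax(zA, zX) < tau
    hyb2 <- !unc2 & pmin(zA, zX) >= tau & abs(zA - zX) < delta
    sub[unc2] <- "unclassified"
    sub[hyb2] <- "hybrid IIA/IIX"
    sub[!unc2 & !hyb2] <- ifelse(zA[!unc2 & !hyb2] >= zX[!unc2 & !hyb2],
                                 "IIA", "IIX")
    tier2[t2] <- sub
  }
  final <- ifelse(tier1 == "type I", "I",
           ifelse(tier1 == "type II", tier2, tier1))
  S4Vectors::DataFrame(cell_id = rownames(scores), tier1 = tier1,
                       tier2 = tier2, final_class = final)
}

.FIBRE_CALL_CLASSES <- c("I", "IIA", "IIX", "hybrid I/IIA", "hybrid IIA/IIX",
                         "unclassified")

#' Per-sample fibre-type proportions
#'
#' For each sample, the fraction of its myonuclei assigned to each final
#' class (`I`, `IIA`, `IIX`, `hybrid I/IIA`, `hybrid IIA/IIX`,
#' `unclassified`). Proportions sum to 1 per sample; samples without
#' myonuclei are excluded with a warning.
#'
#' @param calls `DataFrame` from [classifyFibreTypes()].
#' @param cellMeta cell metadata with `cell_id` and `sample_id` (a `DataFrame`
#'   or the `colData` of the atlas).
#' @return A `DataFrame` with columns `sample_id`, `class`, `proportion`.
#' @export
fibreProportions <- function(calls, cellMeta) {
  samp <- cellMeta$sample_id[match(calls$cell_id, cellMeta$cell_id)]
  if (anyNA(samp)) stop("orphan cell ids: calls not present in cell metadata")
  allSamples <- unique(cellMeta$sample_id)
  empty <- setdiff(allSamples, samp)
  if (length(empty))
    warning("excluding ", length(empty), " sample(s) with zero myonuclei")
  tab <- table(factor(samp), factor(calls$final_class,
                                    levels = .FIBRE_CALL_CLASSES))
  prop <- tab / rowSums(tab)
  S4Vectors::DataFrame(
    sample_id = rep(rownames(prop), times = ncol(prop)),
    class = rep(colnames(prop), each = nrow(prop)),
    proportion = as.numeric(prop))
}

#' Compare per-sample class proportions between age groups
#'
#' Two-tailed Mann-Whitney U-test (via [mannWhitneyU()]) between the adult
#' and old per-sample proportions of one fibre class.
#'
#' @param propTable output of [fibreProportions()].
#' @param sampleMeta sample table with `sample_id` and `age_group`.
#' @param className one of the six final classes.
#' @return A list with `U`, `p` and the per-group sample proportions.
#' @export
compareProportions <- function(propTable, sampleMeta, className) {
  sub <- propTable[propTable$class == className, , drop = FALSE]
  grp <- sampleMeta$age_group[match(sub$sample_id, sampleMeta$sample_id)]
  if (anyNA(grp)) stop("samples in the proportion table lack age_group")
  x <- sub$proportion[grp == "adult"]
  y <- sub$proportion[grp == "old"]
  if (!length(x) || !length(y)) stop("a group has zero samples")
  mw <- mannWhitneyU(x, y)
  list(U = mw$U, p = mw$p, adult = x, old = y)
}
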