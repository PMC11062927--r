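#' @include AllClasses.R
NULL

#' Accessors for agemyo result objects
#'
#' Small accessor family for the S4 result containers: `cellDistances()`
#' extracts the per-cell distance table of a [NoiseResult],
#' `noiseSummary()` its per-group summary row, `compositionEffects()` the
#' effect table of a [CompositionResult], `trendAssignments()` /
#' `trendCentroids()` the labels and centroid matrix of a [TrendClusters],
#' `panelGenes()` the gene ids of a [MarkerPanel].
#'
#' @param x an agemyo result object.
#' @return A `DataFrame`, matrix or character vector, as described above.
#' @name agemyo-accessors
#' @aliases cellDistances noiseSummary compositionEffects trendAssignments
#'   trendCentroids panelGenes
NULL

#' @rdname agemyo-accessors
#' @export
setGeneric("cellDistances", function(x) standardGeneric("cellDistances"))

#' @rdname agemyo-accessors
#' @export
setGeneric("noiseSummary", function(x) standardGeneric("noiseSummary"))

#' @rdname agemyo-accessors
#' @export
setGeneric("compositionEffects", function(x) standardGeneric("compositionEffects"))

#' @rdname agemyo-accessors
#' @export
setGeneric("trendAssignments", function(x) standardGeneric("trendAssignments"))

#' @rdname agemyo-accessors
#' @export
setGeneric("trendCentroids", function(x) standardGeneric("trendCentroids"))

#' @rdname agemyo-accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname agemyo-accessors
setMethod("cellDistances", "NoiseResult", function(x) x@distances)

#' @rdname agemyo-accessors
setMethod("noiseSummary", "NoiseResult", function(x) x@summary)

#' @rdname agemyo-accessors
setMethod("compositionEffects", "CompositionResult", function(x) x@effects)

#' @rdname agemyo-accessors
setMethod("trendAssignments", "TrendClusters", function(x) {
  stats::setNames(x@cluster, x@genes)
})

#' @rdname agemyo-accessors
setMethod("trendCentroids", "TrendClusters", function(x) x@centroids)

#' @rdname agemyo-accessors
setMethod("panelGenes", "MarkerPanel", function(x) x@genes)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", 2L * object@nSamplesPerGroup, "samples (",
      object@nSamplesPerGroup, "per age group ) x",
      object@nCellsPerSample, "cells,", object@nGenes, "genes\n")
  cat("  cell types:", length(object@cellTypeProps),
      "| markerEffect:", object@markerEffect,
      "| hybridFrac:", object@hybridFrac,
      "| seed:", object@seed, "\n")
})

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel '", object@name, "': ", length(object@genes),
      " genes (", paste(utils::head(object@genes, 4L), collapse = ", "),
      if (length(object@genes) > 4L) ", ..." else "", ")\n", sep = "")
})

setMethod("show", "NoiseResult", function(object) {
  s <- object@summary
  cat("NoiseResult for cell type '", object@cellType, "': ",
      nrow(object@distances), " cells, ",
      length(object@invariantGenes), " invariant genes\n", sep = "")
  cat(sprintf("  median adult %.4g | median old %.4g | U = %.1f | p = %.3g\n",
              s$median_adult, s$median_old, s$U, s$p))
})

setMethod("show", "PoissonGLMMFit", function(object) {
  cat("PoissonGLMMFit (", object@inference, "): ",
      length(object@mean), " free parameters, sigma = ",
      signif(object@sigma, 3), if (!object@converged) " [NOT CONVERGED]",
      "\n", sep = "")
})

setMethod("show", "CompositionResult", function(object) {
  cat("CompositionResult:", nrow(object@effects), "effects (",
      object@inference, "inference )\n")
  top <- object@effects[order(-object@effects$ltsr), , drop = FALSE]
  print(utils::head(as.data.frame(top), 5L))
})

setMethod("show", "TrendClusters", function(object) {
  cat("TrendClusters:", length(object@genes), "genes in",
      nrow(object@centroids), "clusters over", ncol(object@centroids),
      "bins; inertia =", signif(object@inertia, 5), "\n")
})
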