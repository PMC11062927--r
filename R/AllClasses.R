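#' @import methods
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Simulation configuration for the synthetic muscle atlas
#'
#' `SimConfig` collects every knob of the synthetic-data generator:
#' sample/cell/gene dimensions, baseline cell-type proportions, per-cell-type
#' abundance log-fold-changes between the two age groups, per
#' (cell type, age group) negative-binomial dispersions, the marker elevation
#' factor, the hybrid-myonucleus fraction, library-size and mitochondrial
#' fraction distributions, pseudotime trend-gene counts, and the seed.
#'
#' The negative binomial is parameterized as mean \eqn{\mu} and dispersion
#' \eqn{\phi} with \eqn{Var = \mu + \phi \mu^2}; \eqn{\phi = 0} degenerates to
#' Poisson. Dispersions are stored as a cell-type x age-group matrix with
#' columns `adult` and `old`.
#'
#' @slot nSamplesPerGroup integer, samples (individuals) per age group.
#' @slot nCellsPerSample integer, cells per sample.
#' @slot nGenes integer, size of the gene universe (the first 1\% of ids,
#'   rounded up, are mitochondrial genes prefixed `"MT-"`).
#' @slot cellTypeProps named numeric, baseline proportions (sum to 1).
#' @slot ageEffects named numeric, old-vs-adult abundance log-fold-changes.
#'   Names may be cell types or fibre types (`I`, `IIA`, `IIX`); fibre-type
#'   entries tilt the fibre mixture within myonuclei of the old group.
#' @slot dispersion numeric matrix (cell types x `c("adult","old")`) of
#'   negative-binomial dispersions \eqn{\phi \ge 0}.
#' @slot markerEffect numeric >= 1, multiplicative elevation of marker genes
#'   in their own cell or fibre type (1 = no marker signal).
#' @slot hybridFrac numeric in \[0,1), fraction of myonuclei simulated as
#'   hybrids (50/50 mixtures of the parent mean vectors).
#' @slot fibreProps named numeric over `c("I","IIA","IIX")`, mixture of pure
#'   fibre types among non-hybrid myonuclei.
#' @slot libsizeLognormal numeric length 2, `(meanlog, sdlog)` of the per-cell
#'   library size.
#' @slot mitoFracBeta numeric length 2, `(a, b)` of the Beta-distributed
#'   per-cell mitochondrial fraction.
#' @slot pseudotimeTrendGenes named integer over
#'   `c("up","down","abrupt","flat")`, genes per trend archetype.
#' @slot seed integer RNG seed; the generator is byte-reproducible given it.
#'
#' @seealso [simConfig()] for the user-facing constructor with study defaults,
#'   [generateAtlas()].
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nSamplesPerGroup = "integer",
    nCellsPerSample = "integer",
    nGenes = "integer",
    cellTypeProps = "numeric",
    ageEffects = "numeric",
    dispersion = "matrix",
    markerEffect = "numeric",
    hybridFrac = "numeric",
    fibreProps = "numeric",
    libsizeLognormal = "numeric",
    mitoFracBeta = "numeric",
    pseudotimeTrendGenes = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSamplesPerGroup < 1L) msg <- c(msg, "nSamplesPerGroup must be >= 1")
  if (object@nCellsPerSample < 1L) msg <- c(msg, "nCellsPerSample must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (is.null(names(object@cellTypeProps)) || any(!nzchar(names(object@cellTypeProps))))
    msg <- c(msg, "cellTypeProps must be a named vector")
  if (abs(sum(object@cellTypeProps) - 1) > 1e-9)
    msg <- c(msg, "cellTypeProps must sum to 1 (within 1e-9)")
  if (any(object@cellTypeProps < 0)) msg <- c(msg, "cellTypeProps must be nonnegative")
  if (any(object@dispersion < 0)) msg <- c(msg, "dispersion phi must be >= 0")
  if (!identical(colnames(object@dispersion), c("adult", "old")))
    msg <- c(msg, "dispersion must have columns 'adult' and 'old'")
  if (!setequal(rownames(object@dispersion), names(object@cellTypeProps)))
    msg <- c(msg, "dispersion rows must match cellTypeProps names")
  if (object@markerEffect < 1)
    msg <- c(msg, "markerEffect must be >= 1 (1 = no marker signal)")
  if (object@hybridFrac < 0 || object@hybridFrac >= 1)
    msg <- c(msg, "hybridFrac must be in [0, 1)")
  if (abs(sum(object@fibreProps) - 1) > 1e-9 ||
      !setequal(names(object@fibreProps), c("I", "IIA", "IIX")))
    msg <- c(msg, "fibreProps must be named I/IIA/IIX and sum to 1")
  if (length(object@libsizeLognormal) != 2L || object@libsizeLognormal[2] < 0)
    msg <- c(msg, "libsizeLognormal must be (meanlog, sdlog >= 0)")
  if (length(object@mitoFracBeta) != 2L || any(object@mitoFracBeta <= 0))
    msg <- c(msg, "mitoFracBeta must be two positive shape parameters")
  if (!setequal(names(object@pseudotimeTrendGenes), c("up", "down", "abrupt", "flat")) ||
      any(object@pseudotimeTrendGenes < 0))
    msg <- c(msg, "pseudotimeTrendGenes must be named up/down/abrupt/flat, nonnegative")
  if (length(msg)) msg else TRUE
})

#' Marker gene panel
#'
#' A named gene set used for module scoring, e.g. one of the four myofibre-type
#' panels shipped by [markerPanels()].
#'
#' @slot name panel name.
#' @slot genes character vector of gene identifiers (non-empty).
#' @seealso [moduleScore()], [markerPanels()]
#' @exportClass MarkerPanel
setClass("MarkerPanel",
  representation(name = "character", genes = "character"))

setValidity("MarkerPanel", function(object) {
  if (length(object@genes) == 0L) return("panel must contain at least one gene")
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})

#' Per-cell heterogeneity ("noise") result
#'
#' Output of [noisePerCell()] / [epigeneticNoisePerCell()]: one Euclidean
#' distance per retained cell after matched downsampling, plus a per-group
#' summary with the two-tailed Mann-Whitney U-test.
#'
#' @slot distances `DataFrame` with columns `cell_id`, `group`, `distance`.
#' @slot summary `DataFrame` with one row: `cell_type`, `median_adult`,
#'   `median_old`, `U`, `p`.
#' @slot cellType the cell type analysed.
#' @slot invariantGenes gene ids over which the distances were computed.
#' @slot seed the seed used for downsampling.
#' @exportClass NoiseResult
setClass("NoiseResult",
  representation(
    distances = "DataFrame",
    summary = "DataFrame",
    cellType = "character",
    invariantGenes = "character",
    seed = "integer"
  )
)

setValidity("NoiseResult", function(object) {
  d <- object@distances
  if (!all(c("cell_id", "group", "distance") %in% colnames(d)))
    return("distances needs columns cell_id, group, distance")
  if (nrow(d) && any(d$distance < 0)) return("distances must be nonnegative")
  TRUE
})

#' Fitted Poisson GLMM posterior for cell-type composition
#'
#' Internal result of [fitPoissonGLMM()]: a Gaussian (Laplace) approximation
#' and/or MCMC draws of the grand-mean-coded composition effects, with the
#' bookkeeping needed to expand the free parameters to per
#' (cell type, factor level) effects.
#'
#' @slot mean posterior mean of the free parameter vector.
#' @slot cov posterior covariance (Laplace) of the free parameters.
#' @slot draws matrix of MCMC draws (0 rows under pure Laplace inference).
#' @slot expansion `DataFrame` mapping expanded effects (cell_type, factor,
#'   level) to rows of `expandMat`.
#' @slot expandMat matrix mapping free parameters to expanded effects.
#' @slot inference `"laplace"` or `"mcmc"`.
#' @slot sigma fitted random-intercept standard deviation.
#' @slot converged logical convergence flag with diagnostics in
#'   `diagnostics`.
#' @slot diagnostics named list (iterations, gradient norm, MCMC acceptance).
#' @exportClass PoissonGLMMFit
setClass("PoissonGLMMFit",
  representation(
    mean = "numeric",
    cov = "matrix",
    draws = "matrix",
    expansion = "DataFrame",
    expandMat = "matrix",
    inference = "character",
    sigma = "numeric",
    converged = "logical",
    diagnostics = "list"
  )
)

#' Composition analysis result
#'
#' Output of [summarizeLTSR()]: per (cell type, factor level) the
#' grand-mean-relative log fold change, fold change, local true sign rate
#' (LTSR) and 95\% credible interval.
#'
#' @slot effects `DataFrame` with columns `cell_type`, `factor`, `level`,
#'   `log_fc`, `fold_change`, `ltsr`, `ci_low`, `ci_high`.
#' @slot inference inference backend the summary came from.
#' @exportClass CompositionResult
setClass("CompositionResult",
  representation(effects = "DataFrame", inference = "character"))

setValidity("CompositionResult", function(object) {
  e <- object@effects
  need <- c("cell_type", "factor", "level", "log_fc", "fold_change",
            "ltsr", "ci_low", "ci_high")
  if (!all(need %in% colnames(e))) return("effects is missing required columns")
  if (nrow(e) && (any(e$ltsr < 0.5 - 1e-12) || any(e$ltsr > 1 + 1e-12)))
    return("LTSR must lie in [0.5, 1]")
  TRUE
})

#' Gene-trend clustering along a pseudotime trajectory
#'
#' Output of [clusterGeneTrends()]: k-means cluster labels of the selected
#' variable genes on their z-scored 100-bin trends, with centroids ordered by
#' the bin index of their peak.
#'
#' @slot genes selected gene ids.
#' @slot cluster integer cluster label per gene (1..k).
#' @slot centroids k x n_bins matrix of centroid trends (z-score units).
#' @slot inertia total within-cluster sum of squares of the kept restart.
#' @exportClass TrendClusters
setClass("TrendClusters",
  representation(
    genes = "character",
    cluster = "integer",
    centroids = "matrix",
    inertia = "numeric"
  )
)

setValidity("TrendClusters", function(object) {
  if (length(object@genes) != length(object@cluster))
    return("one cluster label per gene required")
  k <- nrow(object@centroids)
  if (length(object@cluster) && (min(object@cluster) < 1L || max(object@cluster) > k))
    return("cluster labels out of range")
  TRUE
})
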