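#' @include AllClasses.R
NULL

#' Per-sample cell-type composition counts
#'
#' Cross-tabulation of cells by (sample, cell type), zero-filled, with the
#' per-sample totals and sample-level covariates needed by the Poisson GLMM.
#'
#' @slot counts integer matrix, samples x cell types.
#' @slot totals per-sample cell totals (row sums of `counts`).
#' @slot covariates `DataFrame` of sample covariates, one row per sample.
#' @exportClass CompositionCounts
setClass("CompositionCounts",
  representation(counts = "matrix", totals = "numeric",
                 covariates = "DataFrame"))

setValidity("CompositionCounts", function(object) {
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (!isTRUE(all.equal(as.numeric(rowSums(object@counts)),
                        as.numeric(object@totals))))
    return("totals must equal the count row sums")
  if (nrow(object@covariates) != nrow(object@counts))
    return("one covariate row per sample required")
  TRUE
})

setMethod("show", "CompositionCounts", function(object) {
  cat("CompositionCounts:", nrow(object@counts), "samples x",
      ncol(object@counts), "cell types;",
      sum(object@counts), "cells\n")
})

#' Build composition counts from cell and sample metadata
#'
#' @param cellMeta cell table with `cell_id`, `sample_id`, `cell_type`
#'   (e.g. `colData` of the atlas).
#' @param sampleMeta sample table with `sample_id` and the covariates
#'   (`age_group`, `sex`, `ethnicity`, `modality`, `batch`, ...).
#' @return A [CompositionCounts].
#' @examples
#' sce <- generateAtlas(simConfig(nSamplesPerGroup = 1, nCellsPerSample = 60,
#'                                nGenes = 300, seed = 5))
#' buildCounts(SummarizedExperiment::colData(sce), sampleData(sce))
#' @export
buildCounts <- function(cellMeta, sampleMeta) {
  if (nrow(cellMeta) &&
      !all(cellMeta$sample_id %in% sampleMeta$sample_id))
    stop("orphan cells: sample ids missing from the sample table")
  tab <- table(factor(cellMeta$sample_id, levels = sampleMeta$sample_id),
               factor(cellMeta$cell_type))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  new("CompositionCounts", counts = counts,
      totals = as.numeric(rowSums(counts)),
      covariates = S4Vectors::DataFrame(sampleMeta,
                                        row.names = sampleMeta$sample_id))
}

# Sum-to-zero contrast matrix, n x (n - 1).
.contrSum <- function(n) stats::contr.sum(n)

# Assemble the design for log lambda_{s,c} = log N_s + mu + alpha_c
# + sum_f beta_{f(s),c} + u_s with doubly sum-to-zero (grand-mean) coding of
# every cell-type x factor interaction.
.glmmDesign <- function(cc, factors) {
  counts <- cc@counts
  S <- nrow(counts)
  C <- ncol(counts)
  if (S < 2L || C < 2L) stop("need >= 2 samples and >= 2 cell types")
  types <- colnames(counts)
  y <- as.vector(t(counts))            # sample-major, cell type fastest
  offset <- rep(log(pmax(cc@totals, 1)), each = C)
  Sc <- .contrSum(C)
  X <- cbind(intercept = rep(1, S * C),
             kronecker(matrix(1, S, 1), Sc))
  colnames(X)[-1] <- paste0("alpha_", types[-C])
  blocks <- list(alpha = 1L + seq_len(C - 1L))
  expRows <- list()
  expMats <- list()
  betaFactors <- character()
  for (f in factors) {
    lev <- as.character(cc@covariates[[f]])
    if (is.null(cc@covariates[[f]]))
      stop("factor '", f, "' not found in the sample covariates")
    levels <- sort(unique(lev))
    L <- length(levels)
    cnt <- table(lev)
    if (any(cnt == 1L))
      warning("factor '", f, "' has level(s) present in only one sample: ",
              paste(names(cnt)[cnt == 1L], collapse = ", "))
    if (L < 2L) {
      warning("factor '", f, "' has a single level; skipped")
      next
    }
    SL <- .contrSum(L)
    base <- kronecker(SL, Sc)           # (L*C) x (L-1)(C-1), level-major
    li <- match(lev, levels)
    rowIdx <- rep((li - 1L) * C, each = C) + rep(seq_len(C), times = S)
    Xf <- base[rowIdx, , drop = FALSE]
    colnames(Xf) <- paste0("beta_", f, "_", seq_len(ncol(Xf)))
    blocks[[paste0("beta_", f)]] <- ncol(X) + seq_len(ncol(Xf))
    betaFactors <- c(betaFactors, f)
    X <- cbind(X, Xf)
    expMats[[f]] <- base
    expRows[[f]] <- S4Vectors::DataFrame(
      factor = f,
      level = rep(levels, each = C),
      cell_type = rep(types, times = L))
  }
  if (!length(betaFactors)) stop("no usable factor with >= 2 levels")
  Xu <- kronecker(diag(S), matrix(1, C, 1))
  colnames(Xu) <- paste0("u_", rownames(counts))
  blocks$u <- ncol(X) + seq_len(S)
  X <- cbind(X, Xu)
  list(y = y, X = X, offset = offset, blocks = blocks, S = S, C = C,
       types = types, expMats = expMats, expRows = expRows,
       betaFactors = betaFactors)
}

# Prior precision of the full coefficient vector given the variance
# parameters: sigma (sample random intercept sd) and one tau per factor
# (interaction-effect sd).
.precVector <- function(d, sigma, taus, priorAlpha) {
  prec <- numeric(ncol(d$X))
  prec[1L] <- 1 / 100
  prec[d$blocks$alpha] <- 1 / priorAlpha^2
  for (f in d$betaFactors)
    prec[d$blocks[[paste0("beta_", f)]]] <- 1 / taus[[f]]^2
  prec[d$blocks$u] <- 1 / sigma^2
  prec
}

# Penalized Newton-Raphson fit of the Poisson model at fixed prior precision.
.newtonFit <- function(d, prec, start = NULL, maxIter = 100L, tol = 1e-8) {
  p <- ncol(d$X)
  theta <- if (is.null(start)) numeric(p) else start
  logpost <- function(th) {
    eta <- drop(d$X %*% th) + d$offset
    sum(d$y * eta - exp(pmin(eta, 30))) - 0.5 * sum(prec * th^2)
  }
  lp <- logpost(theta)
  it <- 0L
  for (it in seq_len(maxIter)) {
    eta <- drop(d$X %*% theta) + d$offset
    lam <- exp(pmin(eta, 30))
    grad <- drop(crossprod(d$X, d$y - lam)) - prec * theta
    H <- crossprod(d$X * lam, d$X)
    diag(H) <- diag(H) + prec
    step <- solve(H, grad)
    fac <- 1
    repeat {
      cand <- theta + fac * step
      lpNew <- logpost(cand)
      if (lpNew >= lp - 1e-12 || fac < 1e-6) break
      fac <- fac / 2
    }
    moved <- abs(lpNew - lp)
    theta <- cand
    lp <- lpNew
    if (sqrt(sum(grad^2)) < tol || moved < 1e-12) break
  }
  eta <- drop(d$X %*% theta) + d$offset
  lam <- exp(pmin(eta, 30))
  grad <- drop(crossprod(d$X, d$y - lam)) - prec * theta
  H <- crossprod(d$X * lam, d$X)
  diag(H) <- diag(H) + prec
  list(theta = theta, H = H, logpost = lp,
       gradNorm = sqrt(sum(grad^2)), iterations = it)
}

# Laplace-approximate log marginal over the variance parameters
# v = (log sigma, log tau_1, ...), including the Half-Normal hyperpriors and
# Gaussian normalizing constants that the inner penalized fit omits.
.laplaceMarginal <- function(d, v, priorAlpha, tauPriorSd, env) {
  sigma <- exp(v[1L])
  taus <- stats::setNames(as.list(exp(v[-1L])), d$betaFactors)
  prec <- .precVector(d, sigma, taus, priorAlpha)
  fit <- .newtonFit(d, prec, start = env$warm)
  env$warm <- fit$theta
  env$fit <- fit
  ld <- as.numeric(determinant(fit$H, logarithm = TRUE)$modulus)
  out <- fit$logpost - d$S * log(sigma) - 0.5 * sigma^2 +
    0.5 * ncol(d$X) * log(2 * pi) - 0.5 * ld
  for (f in d$betaFactors) {
    nf <- length(d$blocks[[paste0("beta_", f)]])
    out <- out - nf * log(taus[[f]]) - taus[[f]]^2 / (2 * tauPriorSd^2)
  }
  out
}

# Joint log posterior over (theta, log sigma, log tau_f) for the Metropolis
# sampler; includes Jacobians of the log transforms.
.jointLogPost <- function(d, theta, v, priorAlpha, tauPriorSd) {
  sigma <- exp(v[1L])
  taus <- stats::setNames(as.list(exp(v[-1L])), d$betaFactors)
  prec <- .precVector(d, sigma, taus, priorAlpha)
  eta <- drop(d$X %*% theta) + d$offset
  out <- sum(d$y * eta - exp(pmin(eta, 30))) - 0.5 * sum(prec * theta^2) -
    d$S * log(sigma) - 0.5 * sigma^2 + log(sigma)
  for (f in d$betaFactors) {
    nf <- length(d$blocks[[paste0("beta_", f)]])
    out <- out - nf * log(taus[[f]]) - taus[[f]]^2 / (2 * tauPriorSd^2) +
      log(taus[[f]])
  }
  out
}

#' Fit the Poisson GLMM for cell-type composition
#'
#' Models the count of cell type \eqn{c} in sample \eqn{s} as
#' \deqn{y_{s,c} \sim Poisson(\lambda_{s,c}), \quad
#'   \log\lambda_{s,c} = \log N_s + \mu + \alpha_c +
#'   \sum_f \beta_{f(s),c} + u_s,}
#' with the per-sample total \eqn{N_s} as offset, a sample random intercept
#' \eqn{u_s \sim N(0, \sigma^2)}, and every cell-type x factor interaction
#' under doubly sum-to-zero (grand-mean) coding, so each \eqn{\beta_{l,c}} is
#' the log fold change of cell type \eqn{c} under factor level \eqn{l}
#' relative to the grand mean.
#'
#' The interaction effects of each factor share a scale:
#' \eqn{\beta_{f} \sim N(0, \tau_f^2)} with \eqn{\tau_f \sim} Half-Normal
#' (sd `tauPriorSd`) estimated from the data, exactly like the random
#' intercept sd \eqn{\sigma \sim} Half-Normal(1). This adaptive shrinkage is
#' what keeps the LTSR honest: when a factor carries no compositional signal
#' its \eqn{\tau_f} collapses and every effect is pulled to zero. Passing a
#' numeric `priorBeta` instead fixes \eqn{\tau_f} to that value.
#' \eqn{\alpha_c \sim N(0, 3^2)} throughout.
#'
#' `inference = "laplace"` (the fast default) maximizes the penalized
#' likelihood by Newton iteration, profiles the variance parameters on the
#' Laplace marginal, and returns the Gaussian approximation at the mode.
#' `inference = "mcmc"` additionally runs a preconditioned random-walk
#' Metropolis sampler (proposal shaped by the Laplace covariance, scale
#' adapted during burn-in) over all parameters including the log variance
#' parameters.
#'
#' @param cc a [CompositionCounts] from [buildCounts()].
#' @param factors character vector of covariate columns to model
#'   (default `"age_group"`).
#' @param inference `"laplace"` or `"mcmc"`.
#' @param seed integer seed (MCMC only).
#' @param priorBeta `NULL` for adaptive per-factor shrinkage (default), or a
#'   numeric sd fixing the \eqn{\beta} prior.
#' @param priorAlpha prior sd of the cell-type main effects.
#' @param tauPriorSd sd of the Half-Normal hyperprior on each \eqn{\tau_f}.
#' @param nIter,burnIn MCMC iterations and burn-in.
#' @return A [PoissonGLMMFit]. Non-convergence is reported in the
#'   `converged` flag and `diagnostics`, never silently.
#' @seealso [summarizeLTSR()]
#' @export
fitPoissonGLMM <- function(cc, factors = "age_group",
                           inference = c("laplace", "mcmc"), seed = 1L,
                           priorBeta = NULL, priorAlpha = 3,
                           tauPriorSd = 1.5,
                           nIter = 6000L, burnIn = 1500L) {
  inference <- match.arg(inference)
  d <- .glmmDesign(cc, factors)
  env <- new.env(parent = emptyenv())
  env$warm <- NULL

  nTau <- length(d$betaFactors)
  if (is.null(priorBeta)) {
    obj <- function(v) -.laplaceMarginal(d, v, priorAlpha, tauPriorSd, env)
    opt <- stats::optim(rep(log(0.5), 1L + nTau), obj, method = "L-BFGS-B",
                        lower = rep(log(0.02), 1L + nTau),
                        upper = rep(log(5), 1L + nTau),
                        control = list(factr = 1e10))
    v <- opt$par
  } else {
    fixedTau <- log(priorBeta)
    obj <- function(ls) -.laplaceMarginal(d, c(ls, rep(fixedTau, nTau)),
                                          priorAlpha, tauPriorSd, env)
    ls <- stats::optimize(obj, c(log(0.02), log(5)))$minimum
    v <- c(ls, rep(fixedTau, nTau))
  }
  sigma <- exp(v[1L])
  taus <- stats::setNames(as.list(exp(v[-1L])), d$betaFactors)
  fit <- .newtonFit(d, .precVector(d, sigma, taus, priorAlpha),
                    start = env$warm)
  cov <- solve(fit$H)
  converged <- fit$gradNorm < 1e-4
  if (!converged)
    warning("Newton iteration did not fully converge (gradient norm ",
            signif(fit$gradNorm, 3), " after ", fit$iterations,
            " iterations)")

  betaCols <- unlist(d$blocks[startsWith(names(d$blocks), "beta_")],
                     use.names = FALSE)
  expansion <- do.call(rbind, unname(d$expRows))
  expandMat <- matrix(0, nrow = nrow(expansion), ncol = length(betaCols))
  at <- 0L
  atc <- 0L
  for (f in names(d$expMats)) {
    em <- d$expMats[[f]]
    expandMat[at + seq_len(nrow(em)), atc + seq_len(ncol(em))] <- em
    at <- at + nrow(em)
    atc <- atc + ncol(em)
  }

  draws <- matrix(numeric(0), nrow = 0, ncol = nrow(expansion))
  diagnostics <- list(gradient_norm = fit$gradNorm,
                      newton_iterations = fit$iterations,
                      sigma = sigma, tau = unlist(taus))
  if (inference == "mcmc") {
    .withSeed(seed, {
      p <- ncol(d$X)
      nV <- 1L + nTau
      dAug <- p + nV
      covAug <- matrix(0, dAug, dAug)
      covAug[seq_len(p), seq_len(p)] <- cov
      diag(covAug)[p + seq_len(nV)] <- 0.05^2
      cholC <- chol(covAug + diag(1e-10, dAug))
      scale <- 2.38 / sqrt(dAug)
      cur <- c(fit$theta, v)
      curLp <- .jointLogPost(d, cur[seq_len(p)], cur[p + seq_len(nV)],
                             priorAlpha, tauPriorSd)
      nKeep <- nIter - burnIn
      thin <- max(1L, nKeep %/% 2000L)
      kept <- matrix(NA_real_, nrow = nKeep %/% thin, ncol = length(betaCols))
      acc <- 0L
      ki <- 0L
      for (i in seq_len(nIter)) {
        prop <- cur + scale * drop(stats::rnorm(dAug) %*% cholC)
        propLp <- .jointLogPost(d, prop[seq_len(p)], prop[p + seq_len(nV)],
                                priorAlpha, tauPriorSd)
        if (is.finite(propLp) && log(stats::runif(1)) < propLp - curLp) {
          cur <- prop
          curLp <- propLp
          acc <- acc + 1L
        }
        if (i <= burnIn && i %% 100L == 0L) {
          rate <- acc / i
          scale <- scale * exp(0.5 * (rate - 0.234))
        }
        if (i > burnIn && (i - burnIn) %% thin == 0L && ki < nrow(kept)) {
          ki <- ki + 1L
          kept[ki, ] <- cur[betaCols]
        }
      }
      draws <- kept[seq_len(ki), , drop = FALSE] %*% t(expandMat)
      diagnostics$mcmc_acceptance <- acc / nIter
      diagnostics$mcmc_draws <- ki
    })
  }

  new("PoissonGLMMFit",
      mean = drop(expandMat %*% fit$theta[betaCols]),
      cov = expandMat %*% cov[betaCols, betaCols, drop = FALSE] %*%
        t(expandMat),
      draws = draws,
      expansion = expansion,
      expandMat = expandMat,
      inference = inference,
      sigma = sigma,
      converged = converged,
      diagnostics = diagnostics)
}

#' Summarize a composition fit into fold changes and LTSR
#'
#' For every (cell type, factor level) effect: the grand-mean-relative fold
#' change `exp(posterior mean)`, the local true sign rate
#' `LTSR = max(P(beta > 0), P(beta < 0))` (from MCMC draws when available,
#' else `pnorm(|mean| / sd)` under the Gaussian approximation), and a 95\%
#' credible interval.
#'
#' @param fit a [PoissonGLMMFit].
#' @param ciLevel credible-interval level (default 0.95).
#' @return A [CompositionResult].
#' @export
summarizeLTSR <- function(fit, ciLevel = 0.95) {
  e <- fit@expansion
  a <- (1 - ciLevel) / 2
  if (fit@inference == "mcmc" && nrow(fit@draws) > 0L) {
    mu <- colMeans(fit@draws)
    ltsr <- apply(fit@draws, 2L, function(v)
      max(mean(v > 0) + 0.5 * mean(v == 0), mean(v < 0) + 0.5 * mean(v == 0)))
    ci <- t(apply(fit@draws, 2L, stats::quantile, probs = c(a, 1 - a)))
  } else {
    mu <- fit@mean
    sd <- sqrt(pmax(diag(fit@cov), 0))
    if (any(sd == 0)) stop("degenerate (zero-variance) posterior")
    ltsr <- stats::pnorm(abs(mu) / sd)
    ci <- cbind(mu + stats::qnorm(a) * sd, mu + stats::qnorm(1 - a) * sd)
  }
  new("CompositionResult",
      effects = S4Vectors::DataFrame(
        cell_type = e$cell_type, factor = e$factor, level = e$level,
        log_fc = mu, fold_change = exp(mu), ltsr = pmin(pmax(ltsr, 0.5), 1),
        ci_low = ci[, 1L], ci_high = ci[, 2L]),
      inference = fit@inference)
}

#' Simple cell-type proportions
#'
#' The model-free alternative: each population's share of the total
#' nuclei/cells, either per sample or per dataset (samples aggregated by
#' modality).
#'
#' @param cc a [CompositionCounts].
#' @param by `"sample"` or `"dataset"`.
#' @return A `DataFrame` with columns `group`, `cell_type`, `proportion`;
#'   proportions sum to 1 within each group.
#' @export
simpleProportions <- function(cc, by = c("sample", "dataset")) {
  by <- match.arg(by)
  counts <- cc@counts
  if (by == "dataset") {
    g <- if ("modality" %in% colnames(cc@covariates))
      as.character(cc@covariates$modality) else rep("all", nrow(counts))
    counts <- rowsum(counts, g)
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("zero total in a grouping")
  prop <- counts / totals
  S4Vectors::DataFrame(
    group = rep(rownames(prop), times = ncol(prop)),
    cell_type = rep(colnames(prop), each = nrow(prop)),
    proportion = as.numeric(prop))
}
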