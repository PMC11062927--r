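test_that("null configuration gives balanced group proportions and exact cell conservation", {
  cfg <- simConfig(nSamplesPerGroup = 3L, nCellsPerSample = 2000L,
                   nGenes = 400L,
                   cellTypeProps = c(A = 0.5, B = 0.3, C = 0.2),
                   ageEffects = c(A = 0),
                   dispersionAdult = 0.4, dispersionOld = 0.4,
                   pseudotimeTrendGenes = c(up = 0L, down = 0L, abrupt = 0L,
                                            flat = 0L),
                   seed = 101L)
  sce <- generateAtlas(cfg)
  cd <- SummarizedExperiment::colData(sce)
  sm <- sampleData(sce)

  # conservation: every sample carries exactly nCellsPerSample cells
  expect_true(all(table(cd$sample_id) == 2000L))

  grp <- sm$age_group[match(cd$sample_id, sm$sample_id)]
  for (ty in c("A", "B", "C")) {
    pA <- mean(cd$cell_type[grp == "adult"] == ty)
    pO <- mean(cd$cell_type[grp == "old"] == ty)
    p <- cfg@cellTypeProps[[ty]]
    se <- sqrt(p * (1 - p) * (1 / 6000 + 1 / 6000))
    expect_lt(abs(pA - pO), 3 * se)
  }
})

test_that("markerEffect = 1 produces no fibre-type marker signal", {
  cfg <- myoConfig(seed = 55L, markerEffect = 1, hybridFrac = 0,
                   nSamples = 1L, nCells = 400L,
                   ageEffects = stats::setNames(numeric(0), character(0)))
  sce <- normalizeLog1p(generateAtlas(cfg))
  tr <- simTruth(sce)
  nm <- SummarizedExperiment::assay(sce, "logcounts")
  panelI <- intersect(panelGenes(markerPanels()$I), rownames(nm))
  mI <- Matrix::colMeans(nm[panelI, , drop = FALSE])
  isI <- tr$fibre_type_true == "I"
  isII <- tr$fibre_type_true %in% c("IIA", "IIX")
  expect_gt(stats::t.test(mI[isI], mI[isII])$p.value, 0.01)
})

test_that("doubled old-group dispersion raises the variance/mean ratio, matching a negative-binomial oracle", {
  # Monte-Carlo oracle at the generator's own parameters
  set.seed(77)
  mu <- 5
  vmr <- function(x) stats::var(x) / mean(x)
  oracleAdult <- vmr(stats::rnbinom(1e5, mu = mu, size = 1 / 0.4))
  oracleOld <- vmr(stats::rnbinom(1e5, mu = mu, size = 1 / 0.8))
  expect_gt(oracleOld, oracleAdult)
  # theory: VMR = 1 + phi * mu
  expect_lt(abs(oracleAdult - (1 + 0.4 * mu)) / (1 + 0.4 * mu), 0.05)
  expect_lt(abs(oracleOld - (1 + 0.8 * mu)) / (1 + 0.8 * mu), 0.05)

  sce <- generateAtlas(noiseConfig(seed = 13L, phiAdult = 0.4, phiOld = 0.8))
  cd <- SummarizedExperiment::colData(sce)
  m <- SummarizedExperiment::assay(sce, "counts")
  grp <- sampleData(sce)$age_group[match(cd$sample_id,
                                         sampleData(sce)$sample_id)]
  vmrOf <- function(mm) {
    mu <- Matrix::rowMeans(mm)
    ex2 <- Matrix::rowMeans(mm^2)
    v <- (ex2 - mu^2) * ncol(mm) / (ncol(mm) - 1)
    (v / mu)[mu > 1]
  }
  expect_gt(stats::median(vmrOf(m[, grp == "old"])),
            stats::median(vmrOf(m[, grp == "adult"])))
})

test_that("the generator is byte-deterministic given the seed", {
  cfg <- myoConfig(seed = 42L, nSamples = 1L, nCells = 150L, nGenes = 600L)
  a <- generateAtlas(cfg)
  b <- generateAtlas(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(as.data.frame(simTruth(a)), as.data.frame(simTruth(b)))
  s1 <- generateGeneScores(cfg)
  s2 <- generateGeneScores(cfg)
  expect_identical(SummarizedExperiment::assay(s1, "scores"),
                   SummarizedExperiment::assay(s2, "scores"))
})

test_that("empirical cell-type proportions converge to the configured ones at n = 50,000", {
  cfg <- simConfig(nSamplesPerGroup = 1L, nCellsPerSample = 25000L,
                   nGenes = 250L,
                   cellTypeProps = c(A = 0.5, B = 0.3, C = 0.2),
                   ageEffects = c(A = 0),
                   pseudotimeTrendGenes = c(up = 0L, down = 0L, abrupt = 0L,
                                            flat = 0L),
                   seed = 7L)
  sce <- generateAtlas(cfg)
  ct <- SummarizedExperiment::colData(sce)$cell_type
  n <- length(ct)
  expect_identical(n, 50000L)
  for (ty in names(cfg@cellTypeProps)) {
    p <- cfg@cellTypeProps[[ty]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(ct == ty) - p), 3 * se)
  }
})

test_that("a naive argmax marker classifier recovers pure fibre types, so the fixture is learnable", {
  cfg <- myoConfig(seed = 11L, nSamples = 1L, nCells = 600L,
                   markerEffect = 4, phi = 0.5, hybridFrac = 0)
  sce <- normalizeLog1p(generateAtlas(cfg))
  nm <- t(scale(t(as.matrix(
    SummarizedExperiment::assay(sce, "logcounts")))))  # per-gene z-scores
  tr <- simTruth(sce)
  panels <- markerPanels()[c("I", "IIA", "IIX")]
  means <- sapply(panels, function(p)
    colMeans(nm[intersect(panelGenes(p), rownames(nm)), , drop = FALSE]))
  called <- colnames(means)[max.col(means)]
  acc <- mean(called == tr$fibre_type_true)
  expect_gte(acc, 0.95)
})

test_that("gene-activity scores are nonnegative, reproducible, and exact at zero dispersion", {
  cfg <- noiseConfig(seed = 9L, phiAdult = 0, phiOld = 0, nCells = 50L,
                     nGenes = 300L)
  gs <- generateGeneScores(cfg)
  sc <- SummarizedExperiment::assay(gs, "scores")
  expect_true(all(sc@x >= 0))
  # phi = 0 degenerates the gamma to its mean: library-size scaling only,
  # so per-cell totals match the drawn library sizes (no count noise)
  rounded <- agemyo:::.roundHalfAway(as.matrix(sc))
  expect_true(all(rounded == floor(abs(rounded)) * sign(rounded)))
  expect_identical(sum(rounded), sum(agemyo:::.roundHalfAway(as.matrix(sc))))
})

test_that("fixture write/read round-trips exactly and is byte-stable across runs", {
  cfg <- myoConfig(seed = 21L, nSamples = 1L, nCells = 60L, nGenes = 500L)
  sce <- generateAtlas(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- writeFixture(sce, d1)
  expect_identical(man$seed, 21L)
  writeFixture(generateAtlas(cfg), d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "matrix.mtx"))),
                   unname(tools::md5sum(file.path(d2, "matrix.mtx"))))

  back <- readAtlas(d1)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_identical(colnames(back), colnames(sce))
  expect_equal(simTruth(back)$pseudotime_true, simTruth(sce)$pseudotime_true)
})

test_that("a toy fixture writes the expected MatrixMarket header", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 3), j = c(1, 1, 1, 2),
                            x = c(1, 2, 3, 5), dims = c(3, 2))
  rownames(m) <- c("g1", "g2", "g3")
  colnames(m) <- c("c1", "c2")
  cd <- S4Vectors::DataFrame(cell_id = colnames(m), sample_id = "s1",
                             cell_type = "A", modality = "snRNA",
                             row.names = colnames(m))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
  d <- withr::local_tempdir()
  writeFixture(sce, d)
  lines <- readLines(file.path(d, "matrix.mtx"), n = 2L)
  expect_identical(lines[2], "3 2 4")
})
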