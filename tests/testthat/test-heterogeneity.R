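test_that("Mann-Whitney U and exact p match brute-force enumeration", {
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4), mode = "exact"),
               list(U = 0, p = 1 / 3, method = "exact"))

  # randomized battery against the pair-counting/enumeration oracle
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    m <- sample(1:6, 1)
    x <- sample(1:5, n, replace = TRUE)  # heavy ties
    y <- sample(1:5, m, replace = TRUE)
    got <- mannWhitneyU(x, y, mode = "exact")
    expect_equal(got$U, mwOracleU(x, y))
    expect_equal(got$p, mwOracleP(x, y))
  }
})

test_that("Mann-Whitney identities and degenerate cases hold", {
  set.seed(3)
  for (rep in 1:20) {
    x <- sample(1:6, sample(2:8, 1), replace = TRUE)
    y <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(mannWhitneyU(x, y)$U + mannWhitneyU(y, x)$U,
                 length(x) * length(y))
  }
  expect_equal(mannWhitneyU(rep(2, 4), rep(2, 4))$p, 1)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")

  # tie-free agreement with the reference implementation
  set.seed(8)
  x <- rnorm(6)
  y <- rnorm(6)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  got <- mannWhitneyU(x, y, mode = "exact")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)

  # large-sample normal mode against the reference with continuity correction
  x <- rnorm(40)
  y <- rnorm(35) + 0.5
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  got <- mannWhitneyU(x, y, mode = "normal_tie_corrected")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("invariant-gene selection partitions by expression and picks lowest CV", {
  # 100 expressed genes, 10 blocks, 10% -> exactly 10 genes
  set.seed(4)
  m <- Matrix::Matrix(matrix(rpois(100 * 30, lambda = rep(1:100, 30)) + 1,
                             nrow = 100,
                             dimnames = list(sprintf("g%03d", 1:100), NULL)),
                      sparse = TRUE)
  sel <- selectInvariantGenes(m, nBlocks = 10, lowestFrac = 0.1)
  expect_identical(nrow(sel), 10L)
  expect_identical(sort(unique(sel$block)), 1:10)

  # a constant gene (CV = 0) is always selected within its block
  m2 <- as.matrix(m)
  m2["g050", ] <- 50
  sel2 <- selectInvariantGenes(Matrix::Matrix(m2, sparse = TRUE))
  expect_true("g050" %in% sel2$gene)

  # 20-gene worked example against an independent computation
  set.seed(9)
  w <- matrix(rlnorm(20 * 12), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:12)))
  sel3 <- selectInvariantGenes(Matrix::Matrix(w, sparse = TRUE),
                               nBlocks = 4, lowestFrac = 0.25)
  mu <- rowMeans(w)
  cv <- apply(w, 1, sd) / mu
  ord <- order(mu, rownames(w))
  expected <- unlist(lapply(0:3, function(b) {
    blk <- ord[b * 5 + 1:5]
    blk[order(cv[blk], rownames(w)[blk])][1:2]  # ceiling(0.25 * 5) = 2
  }))
  expect_setequal(sel3$gene, rownames(w)[expected])
  expect_equal(sel3$cv, unname(cv[sel3$gene]))
})

test_that("noise distances vanish for identical cells and are duplication-invariant", {
  base <- matrix(rep(c(5, 3, 2, 7, 1, 2, 4, 6, 2, 8), 8), nrow = 10)
  a <- base[, 1:4]
  o <- base[, 1:4]
  sce <- twoGroupSCE(a, o)
  nr <- noisePerCell(sce, "MuSC", nMax = 10, seed = 1)
  expect_true(all(cellDistances(nr)$distance == 0))
  expect_equal(noiseSummary(nr)$p, 1)

  # distinct cells: duplicating every cell leaves each distance unchanged
  set.seed(6)
  a <- matrix(rpois(10 * 6, 5), nrow = 10)
  a[1, ] <- a[1, ] + max(colSums(a)) - colSums(a)  # equal totals, no depth DS
  o <- a + 0
  sce1 <- twoGroupSCE(a, o)
  r1 <- noisePerCell(sce1, "MuSC", nMax = 100, seed = 2)
  sce2 <- twoGroupSCE(cbind(a, a), cbind(o, o))
  r2 <- noisePerCell(sce2, "MuSC", nMax = 100, seed = 2)
  d1 <- cellDistances(r1)$distance[1:6]
  d2 <- cellDistances(r2)$distance[1:6]
  expect_equal(d1, d2)
})

test_that("the noise pipeline is seed-reproducible and group-relabel equivariant", {
  sce <- generateAtlas(noiseConfig(seed = 31L, nCells = 80L, nGenes = 400L))
  r1 <- noisePerCell(sce, "MuSC", nMax = 60, seed = 5)
  r2 <- noisePerCell(sce, "MuSC", nMax = 60, seed = 5)
  expect_identical(cellDistances(r1), cellDistances(r2))

  # swap the group labels: distances unchanged per cell, U -> nm - U
  swapped <- sce
  sm <- S4Vectors::metadata(swapped)$samples
  sm$age_group <- c(adult = "old", old = "adult")[sm$age_group]
  S4Vectors::metadata(swapped)$samples <- sm
  r3 <- noisePerCell(swapped, "MuSC", nMax = 60, seed = 5)
  d1 <- cellDistances(r1)
  d3 <- cellDistances(r3)
  shared <- intersect(d1$cell_id, d3$cell_id)
  expect_equal(d3$distance[match(shared, d3$cell_id)],
               d1$distance[match(shared, d1$cell_id)])
  n1 <- sum(d1$group == "adult")
  expect_equal(noiseSummary(r3)$U,
               n1 * (nrow(d1) - n1) - noiseSummary(r1)$U)
})

test_that("rounding is half-away-from-zero and integer input reduces the epigenetic arm to the transcriptional one", {
  expect_equal(agemyo:::.roundHalfAway(c(2.5, 2.49, -2.5, -2.49, 0.5)),
               c(3, 2, -3, -2, 1))

  sce <- generateAtlas(noiseConfig(seed = 17L, nCells = 60L, nGenes = 350L))
  gs <- sce
  SummarizedExperiment::assayNames(gs) <- "scores"
  rT <- noisePerCell(sce, "MuSC", nMax = 50, seed = 3)
  rE <- epigeneticNoisePerCell(gs, "MuSC", nMax = 50, seed = 3)
  expect_equal(cellDistances(rT)$distance, cellDistances(rE)$distance)
})

test_that("doubled gamma variance in the old group raises epigenetic noise", {
  cfg <- noiseConfig(seed = 23L, phiAdult = 0.3, phiOld = 0.6,
                     nCells = 200L, nGenes = 400L)
  gs <- generateGeneScores(cfg)
  r <- epigeneticNoisePerCell(gs, "MuSC", nMax = 200, seed = 4)
  s <- noiseSummary(r)
  expect_gt(s$median_old, s$median_adult)
  expect_lt(s$p, 0.01)
})

test_that("noise detection is more powerful at 300 cells per group than at 50", {
  rejAt <- function(nCells, seeds) {
    mean(vapply(seeds, function(s) {
      sce <- generateAtlas(noiseConfig(seed = s, phiAdult = 0.4,
                                       phiOld = 0.6, nCells = nCells,
                                       nGenes = 300L))
      noiseSummary(noisePerCell(sce, "MuSC", nMax = nCells, seed = s))$p < 0.01
    }, logical(1)))
  }
  seeds <- 300 + 1:15
  expect_gte(rejAt(300L, seeds), rejAt(50L, seeds))
})
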