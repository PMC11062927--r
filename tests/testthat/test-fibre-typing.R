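test_that("module scores vanish when controls cannot differ and equal the shift otherwise", {
  # every gene identical -> any control draw equals the panel mean -> score 0
  m <- matrix(rep(seq(0.5, 2.4, by = 0.1), times = 25), nrow = 25,
              byrow = TRUE,
              dimnames = list(sprintf("g%02d", 1:25), sprintf("c%02d", 1:20)))
  sc <- moduleScore(Matrix::Matrix(m, sparse = TRUE),
                    c("g03", "g07", "g11"), nBins = 1, nCtrl = 10, seed = 2)
  expect_equal(unname(sc), rep(0, 20))

  # panel genes k above their bin mates in one cell -> score exactly k
  m2 <- m
  m2[c("g03", "g07", "g11"), "c01"] <- m2[c("g03", "g07", "g11"), "c01"] + 1.5
  sc2 <- moduleScore(Matrix::Matrix(m2, sparse = TRUE),
                     c("g03", "g07", "g11"), nBins = 1, nCtrl = 10, seed = 2)
  expect_equal(unname(sc2["c01"]), 1.5)
  expect_equal(unname(sc2["c02"]), 0)

  # absent panel errors; partially absent warns
  expect_error(moduleScore(Matrix::Matrix(m, sparse = TRUE), c("nope")),
               "no panel gene")
  expect_warning(moduleScore(Matrix::Matrix(m, sparse = TRUE),
                             c("g03", "nope"), nBins = 1, seed = 1),
                 "dropping")
})

test_that("module scores match a straight-line reimplementation and separate true fibre types", {
  cfg <- myoConfig(seed = 101L, nSamples = 1L, nCells = 300L, hybridFrac = 0)
  sce <- normalizeLog1p(generateAtlas(cfg))
  nm <- SummarizedExperiment::assay(sce, "logcounts")
  sc <- moduleScore(nm, markerPanels()$I, nBins = 25, nCtrl = 100, seed = 7)

  # independent reimplementation of the same formula, same seed
  reimpl <- local({
    genes <- intersect(panelGenes(markerPanels()$I), rownames(nm))
    mu <- Matrix::rowMeans(nm)
    ord <- order(mu, rownames(nm))
    bin <- integer(length(mu))
    bin[ord] <- ceiling(seq_along(mu) * 25 / length(mu))
    idx <- match(genes, rownames(nm))
    old <- .Random.seed
    set.seed(7)
    ctrl <- unlist(lapply(idx, function(i) {
      mates <- setdiff(which(bin == bin[i]), idx)
      if (length(mates) >= 100) sample(mates, 100)
      else sample(mates, 100, replace = TRUE)
    }))
    .Random.seed <<- old
    dense <- as.matrix(nm)
    colMeans(dense[idx, , drop = FALSE]) - colMeans(dense[ctrl, , drop = FALSE])
  })
  expect_equal(unname(sc), unname(reimpl))

  tr <- simTruth(sce)
  expect_gt(mean(sc[tr$fibre_type_true == "I"]),
            mean(sc[tr$fibre_type_true %in% c("IIA", "IIX")]))
})

test_that("the hierarchical classifier follows its decision rules", {
  set.seed(12)
  n <- 400
  sc <- cbind(I = rnorm(n), II = rnorm(n), IIA = rnorm(n), IIX = rnorm(n))
  rownames(sc) <- sprintf("c%03d", seq_len(n))

  # dominant type I score (well above the others) -> type I
  sc1 <- sc
  sc1["c001", ] <- c(8, -1, -1, -1)
  calls <- classifyFibreTypes(sc1, tau = 0, delta = 0.5)
  expect_identical(calls$tier1[calls$cell_id == "c001"], "type I")
  expect_identical(calls$tier2[calls$cell_id == "c001"], "n/a")

  # tau above every z-score -> everything unclassified
  callsAll <- classifyFibreTypes(sc, tau = 99, delta = 0.5)
  expect_true(all(callsAll$tier1 == "unclassified"))
  expect_true(all(callsAll$final_class == "unclassified"))

  # structural invariant: tier2 is n/a exactly for non-type-II tier1
  calls2 <- classifyFibreTypes(sc, tau = 0, delta = 0.5)
  expect_identical(calls2$tier2 == "n/a", calls2$tier1 != "type II")

  # invariance to per-panel affine rescaling before z-standardization
  scAff <- sweep(sweep(sc, 2, c(2, 0.5, 3, 10), "*"), 2, c(1, -4, 0, 7), "+")
  expect_identical(as.data.frame(classifyFibreTypes(scAff)),
                   as.data.frame(calls2))

  # raising tau weakly increases the unclassified fraction
  fracU <- vapply(c(-1, 0, 0.5, 1, 2), function(tau)
    mean(classifyFibreTypes(sc, tau = tau)$final_class == "unclassified"),
    numeric(1))
  expect_true(all(diff(fracU) >= 0))
})

test_that("fibre proportions are per-sample simplexes with exact arithmetic", {
  calls <- S4Vectors::DataFrame(
    cell_id = c("c1", "c2", "c3", "c4"),
    tier1 = c("type I", "type I", "type II", "type II"),
    tier2 = c("n/a", "n/a", "IIA", "IIX"),
    final_class = c("I", "I", "IIA", "IIX"))
  cellMeta <- S4Vectors::DataFrame(cell_id = c("c1", "c2", "c3", "c4"),
                                   sample_id = "s1")
  prop <- fibreProportions(calls, cellMeta)
  p <- stats::setNames(prop$proportion, prop$class)
  expect_equal(unname(p[c("I", "IIA", "IIX")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(prop$proportion), 1)

  # samples without myonuclei are excluded with a warning
  cellMeta2 <- rbind(cellMeta,
                     S4Vectors::DataFrame(cell_id = "c9", sample_id = "s2"))
  expect_warning(fibreProportions(calls, cellMeta2), "zero myonuclei")

  # orphan calls error
  expect_error(
    fibreProportions(rbind(calls, S4Vectors::DataFrame(
      cell_id = "zz", tier1 = "type I", tier2 = "n/a", final_class = "I")),
      cellMeta),
    "orphan")
})

test_that("group comparison of proportions reduces to the Mann-Whitney test", {
  prop <- S4Vectors::DataFrame(
    sample_id = c("a1", "a2", "o1", "o2"),
    class = "IIX",
    proportion = c(0.1, 0.2, 0.3, 0.4))
  sm <- S4Vectors::DataFrame(sample_id = c("a1", "a2", "o1", "o2"),
                             age_group = c("adult", "adult", "old", "old"))
  res <- compareProportions(prop, sm, "IIX")
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)

  # identical proportions in both groups -> p = 1
  prop$proportion <- rep(0.25, 4)
  expect_equal(compareProportions(prop, sm, "IIX")$p, 1)

  # label swap keeps p and maps U to nm - U
  prop$proportion <- c(0.1, 0.2, 0.3, 0.4)
  smSwap <- sm
  smSwap$age_group <- rev(sm$age_group)
  res2 <- compareProportions(prop, smSwap, "IIX")
  expect_equal(res2$U, 4 - res$U)
  expect_equal(res2$p, res$p)
})

test_that("pure fibre classes are recovered on the synthetic atlas at defaults", {
  cfg <- myoConfig(seed = 404L, nSamples = 5L, nCells = 500L,
                   markerEffect = 4, phi = 0.4, hybridFrac = 0.1)
  sce <- normalizeLog1p(generateAtlas(cfg))
  sc <- fibreModuleScores(sce, seed = 5)
  calls <- classifyFibreTypes(sc)
  tr <- simTruth(sce)
  tr <- tr[match(calls$cell_id, tr$cell_id), ]
  pure <- tr$fibre_type_true %in% c("I", "IIA", "IIX")
  acc <- mean(calls$final_class[pure] == tr$fibre_type_true[pure])
  expect_gte(acc, 0.9)
})
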