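test_that("simulator parameters are validated", {
  expect_error(scSimParams(nCellTypes = 10L, nGenes = 50L,
                           nMarkersPerType = 10L),
               class = "murideconv_validation_error")
  expect_error(scSimParams(markerFold = 0.5),
               class = "murideconv_validation_error")
  expect_error(scSimParams(nbDispersion = 0),
               class = "murideconv_validation_error")
})

test_that("Poisson-mode marker means match the generative model", {
  p <- scSimParams(nCellTypes = 2L, nGenes = 200L, nMarkersPerType = 10L,
                   markerFold = 6, baseMean = 4, nbDispersion = Inf,
                   libsizeSigma = 0, nCellsPerType = 500L, seed = 17L)
  ref <- simulateSCReference(p)
  m <- as.matrix(ref$expr)
  markers <- ref$plantedMarkers$typeA
  cellsA <- names(ref$labels)[ref$labels == "typeA"]
  mu_hat <- mean(m[markers, cellsA])
  mu_true <- 4 * 6
  se <- sqrt(mu_true / (length(markers) * length(cellsA)))
  expect_lt(abs(mu_hat - mu_true), 3 * se)
  # background genes stay at baseMean
  bg <- setdiff(rownames(m), unlist(ref$plantedMarkers))
  expect_lt(abs(mean(m[bg, cellsA]) - 4),
            3 * sqrt(4 / (length(bg) * length(cellsA))))
})

test_that("simulation is reproducible from its seed", {
  p <- scSimParams(nCellTypes = 2L, nGenes = 50L, nMarkersPerType = 5L,
                   nCellsPerType = 20L, seed = 99L)
  r1 <- simulateSCReference(p)
  r2 <- simulateSCReference(p)
  expect_identical(as.matrix(r1$expr), as.matrix(r2$expr))
  pb1 <- simulatePseudobulk(r1$expr, r1$labels, nSamples = 3L,
                            nCellsPerSample = 50L, seed = 5L)
  pb2 <- simulatePseudobulk(r2$expr, r2$labels, nSamples = 3L,
                            nCellsPerSample = 50L, seed = 5L)
  expect_identical(as.matrix(pb1@expr), as.matrix(pb2@expr))
  expect_identical(trueFractions(pb1, "cells"), trueFractions(pb2, "cells"))
})

test_that("without type separability the signature builder must fail", {
  p <- scSimParams(nCellTypes = 2L, nGenes = 100L, nMarkersPerType = 5L,
                   markerFold = 1, nCellsPerType = 30L, seed = 23L)
  ref <- simulateSCReference(p)
  expect_error(buildSignatureFromSC(ref$expr, ref$labels, minFold = 2),
               class = "murideconv_validation_error")
})

test_that("pseudo-bulk columns conserve the sampled cells' mass exactly", {
  p <- scSimParams(nCellTypes = 3L, nGenes = 80L, nMarkersPerType = 5L,
                   nCellsPerType = 25L, seed = 31L)
  ref <- simulateSCReference(p)
  pb <- simulatePseudobulk(ref$expr, ref$labels, nSamples = 4L,
                           nCellsPerSample = 60L, seed = 8L)
  m <- as.matrix(pb@expr)
  # with unit mRNA bias, each column total is a sum of integer cell totals
  expect_true(all(m == round(m)))
  expect_identical(unname(colSums(trueFractions(pb, "cells"))), rep(1, 4))
  # fraction matrices are column-stochastic
  expect_equal(unname(colSums(trueFractions(pb, "mrna"))), rep(1, 4),
               tolerance = 1e-9)
})

test_that("single-cell pseudo-bulk degenerates to one cell's profile", {
  p <- scSimParams(nCellTypes = 2L, nGenes = 40L, nMarkersPerType = 4L,
                   nCellsPerType = 15L, seed = 37L)
  ref <- simulateSCReference(p)
  pb <- simulatePseudobulk(ref$expr, ref$labels, nSamples = 1L,
                           nCellsPerSample = 1L, seed = 2L)
  col <- as.matrix(pb@expr)[, 1]
  sc <- as.matrix(ref$expr)
  match_any <- any(apply(sc, 2, function(x) all(x == col)))
  expect_true(match_any)
  # exactly one type realized
  expect_identical(sort(unname(trueFractions(pb, "cells")[, 1])), c(0, 1))
})

test_that("mRNA bias reweights ground truth by closed form", {
  # hand-built reference: identical library sizes within and across types
  genes <- paste0("g", 1:4)
  cells <- paste0("c", 1:8)
  m <- matrix(0, 4, 8, dimnames = list(genes, cells))
  m[1, 1:4] <- 10; m[2, 1:4] <- 10       # type A cells: total 20
  m[3, 5:8] <- 10; m[4, 5:8] <- 10       # type B cells: total 20
  labels <- setNames(rep(c("A", "B"), each = 4), cells)
  sc <- ExpressionMatrix(m, "counts")
  pb <- simulatePseudobulk(sc, labels, fractions = c(A = 0.5, B = 0.5),
                           nSamples = 5L, nCellsPerSample = 40L,
                           mrnaBias = c(A = 2, B = 1), seed = 3L)
  cells_frac <- trueFractions(pb, "cells")
  mrna_frac <- trueFractions(pb, "mrna")
  # closed form: bias x equal mean library size, renormalized
  expected_A <- 2 * cells_frac["A", ] /
    (2 * cells_frac["A", ] + 1 * cells_frac["B", ])
  expect_equal(mrna_frac["A", ], expected_A, tolerance = 1e-12)
  # with unit bias the two flavors coincide exactly (equal library sizes)
  pb2 <- simulatePseudobulk(sc, labels, fractions = c(A = 0.5, B = 0.5),
                            nSamples = 3L, nCellsPerSample = 40L, seed = 4L)
  expect_equal(trueFractions(pb2, "mrna"), trueFractions(pb2, "cells"),
               tolerance = 1e-12)
})

test_that("requesting a type absent from the reference errors by name", {
  p <- scSimParams(nCellTypes = 2L, nGenes = 30L, nMarkersPerType = 3L,
                   nCellsPerType = 12L, seed = 41L)
  ref <- simulateSCReference(p)
  expect_error(simulatePseudobulk(ref$expr, ref$labels,
                                  fractions = c(typeA = 0.5, typeZ = 0.5),
                                  nSamples = 2L, nCellsPerSample = 10L),
               "typeZ")
})

test_that("realized fractions converge to requested proportions", {
  p <- scSimParams(nCellTypes = 3L, nGenes = 30L, nMarkersPerType = 3L,
                   nCellsPerType = 15L, seed = 43L)
  ref <- simulateSCReference(p)
  req <- c(typeA = 0.2, typeB = 0.3, typeC = 0.5)
  pb <- simulatePseudobulk(ref$expr, ref$labels, fractions = req,
                           nSamples = 1L, nCellsPerSample = 10000L, seed = 6L)
  expect_lt(max(abs(trueFractions(pb, "cells")[, 1] - req)), 0.02)
})
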