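test_that("bundled resources expose the documented cell-type cardinalities", {
  lst <- listResources()
  expect_setequal(lst$name, c("mmcp_like", "seqimmucc_like", "finegrained_like"))

  mk <- getResource("mmcp_like")
  expect_s4_class(mk, "WeightedGeneSetCollection")
  expect_length(cellTypes(mk), 14L)

  sig <- getResource("seqimmucc_like")
  expect_s4_class(sig, "SignatureMatrix")
  expect_length(cellTypes(sig), 10L)
  # TPM-like contract: columns sum to 1e6
  expect_equal(unname(colSums(as.matrix(sig))), rep(1e6, 10), tolerance = 1e-6)

  roster <- getResource("finegrained_like")
  expect_gt(length(unique(roster$fine)), 180L)
  expect_true(all(roster$major %in% majorRoster(defaultOntology())))
})

test_that("unknown resource names suggest the closest match", {
  expect_error(getResource("nope"), "did you mean")
  expect_error(getResource("mmcp_lik"), "mmcp_like")
})

test_that("an exclusively expressed gene becomes its type's top marker", {
  set.seed(2)
  nc <- 24L
  counts <- matrix(rpois(50 * nc, 5), 50, nc,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%02d", 1:nc)))
  labels <- setNames(rep(c("A", "B"), each = nc / 2), colnames(counts))
  counts["g01", labels == "A"] <- 80      # exclusive to A
  counts["g01", labels == "B"] <- 0
  built <- buildSignatureFromSC(ExpressionMatrix(counts, "counts"), labels,
                                nMarkersPerType = 1L, minFold = 2)
  expect_identical(names(geneSets(built$markers)$A), "g01")
  expect_equal(as.matrix(built$signature)["g01", "B"], 0)
})

test_that("the builder recovers planted marker blocks from simulation", {
  ref <- simulateSCReference(scSimParams(nCellTypes = 3L, nGenes = 300L,
                                         nMarkersPerType = 20L,
                                         markerFold = 8, baseMean = 3,
                                         nbDispersion = 5,
                                         nCellsPerType = 60L, seed = 42L))
  built <- buildSignatureFromSC(ref$expr, ref$labels, nMarkersPerType = 20L,
                                minFold = 2)
  for (t in names(ref$plantedMarkers)) {
    hit <- intersect(names(geneSets(built$markers)[[t]]),
                     ref$plantedMarkers[[t]])
    expect_gte(length(hit), 18L)
  }
  # every selected marker satisfies the fold criterion against max-of-others
  cpm <- sweep(as.matrix(ref$expr), 2, colSums(as.matrix(ref$expr)), "/") * 1e6
  types <- sort(unique(ref$labels))
  M <- vapply(types, function(t)
    rowMeans(cpm[, ref$labels == t, drop = FALSE]), numeric(nrow(cpm)))
  for (t in types) {
    g <- names(geneSets(built$markers)[[t]])
    others <- apply(M[g, setdiff(types, t), drop = FALSE], 1, max)
    expect_true(all(M[g, t] >= 2 * others))
  }
})

test_that("builder errors name the offending cell type or threshold", {
  ref <- simulateSCReference(scSimParams(nCellTypes = 2L, nGenes = 100L,
                                         nMarkersPerType = 5L,
                                         nCellsPerType = 12L, seed = 3L))
  expect_error(buildSignatureFromSC(ref$expr, ref$labels, minFold = Inf),
               class = "murideconv_validation_error")
  # a type with too few cells
  small <- ref$labels
  small[small == "typeB"][1:4] <- "typeC"
  expect_error(buildSignatureFromSC(ref$expr, small), "typeC")
  # fewer than 2 types
  expect_error(buildSignatureFromSC(ref$expr,
                                    setNames(rep("A", ncol(as.matrix(ref$expr))),
                                             colnames(as.matrix(ref$expr)))),
               "2 cell types")
})

test_that("the builder is deterministic under identical input ordering", {
  ref <- simulateSCReference(scSimParams(nCellTypes = 2L, nGenes = 120L,
                                         nMarkersPerType = 10L,
                                         nCellsPerType = 15L, seed = 9L))
  b1 <- buildSignatureFromSC(ref$expr, ref$labels, nMarkersPerType = 10L)
  b2 <- buildSignatureFromSC(ref$expr, ref$labels, nMarkersPerType = 10L)
  expect_identical(as.matrix(b1$signature), as.matrix(b2$signature))
  expect_identical(geneSets(b1$markers), geneSets(b2$markers))
})

test_that("signature coverage reports present fractions and warns", {
  sig <- makeSignature(K = 2L, G = 10L, seed = 5L)
  full <- mixtureFrom(sig, c(0.5, 0.5))
  cov <- validateSignatureCoverage(sig, full)
  expect_equal(cov$overall, 1)
  expect_false(cov$warning)

  half <- ExpressionMatrix(as.matrix(full)[1:5, , drop = FALSE], "TPM")
  expect_warning(validateSignatureCoverage(sig, half), "50%")
  cov2 <- suppressWarnings(validateSignatureCoverage(sig, half))
  expect_equal(cov2$overall, 0.5)
  expect_true(cov2$warning)

  none <- ExpressionMatrix(matrix(1, 2, 1, dimnames = list(c("zz1", "zz2"),
                                                           "s1")), "TPM")
  cov3 <- suppressWarnings(validateSignatureCoverage(sig, none))
  expect_equal(cov3$overall, 0)
  # engines refuse to run on an empty intersection
  expect_error(clsDeconvolve(none, sig), class = "murideconv_coverage_error")
})
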