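test_that("self-mixtures and exact linear mixtures are recovered to 1e-6", {
  sig <- makeSignature(K = 2L, G = 20L, seed = 7L)
  # pure self-mixture with unknown allowed
  em <- mixtureFrom(sig, c(1, 0))
  res <- clsDeconvolve(em, sig, allowUnknown = TRUE)
  f <- as.matrix(res)[, 1]
  expect_equal(unname(f), c(1, 0, 0), tolerance = 1e-6)
  # 0.3 / 0.7 mixture
  em2 <- mixtureFrom(sig, c(0.3, 0.7))
  f2 <- as.matrix(clsDeconvolve(em2, sig))[, 1]
  expect_equal(unname(f2), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("cls fraction columns satisfy the simplex invariants", {
  sig <- makeSignature(K = 4L, G = 40L, seed = 3L)
  S <- as.matrix(sig)
  B <- vapply(1:6, function(i) as.vector(S %*% randomFractions(4, i)) *
                runif(1, 0.5, 2), numeric(nrow(S)))
  dimnames(B) <- list(rownames(S), paste0("s", 1:6))
  em <- ExpressionMatrix(B, "TPM")
  strict <- clsDeconvolve(em, sig)
  expect_equal(unname(colSums(as.matrix(strict))), rep(1, 6),
               tolerance = 1e-9)
  loose <- clsDeconvolve(em, sig, allowUnknown = TRUE)
  expect_equal(unname(colSums(as.matrix(loose))), rep(1, 6),
               tolerance = 1e-9)
  expect_true(all(as.matrix(loose) >= -1e-12))
})

test_that("cls agrees with the simplex grid-search oracle", {
  for (i in 1:5) {
    K <- 2L + (i %% 2L)
    sig <- makeSignature(K = K, G = 20L, seed = 100L + i, separation = 8)
    f_true <- randomFractions(K, 200L + i)
    S <- as.matrix(sig)
    set.seed(300L + i)
    b <- as.vector(S %*% f_true) * exp(rnorm(nrow(S), 0, 0.15))  # noisy
    b <- b / sum(b) * 1e6
    em <- ExpressionMatrix(matrix(b, ncol = 1,
                                  dimnames = list(rownames(S), "s1")), "TPM")
    f_hat <- as.matrix(clsDeconvolve(em, sig))[, 1]
    f_oracle <- gridSearchCLS(S / 1e6, b / 1e6, step = 0.01)
    expect_lt(max(abs(f_hat - f_oracle)), 0.02)
  }
})

test_that("unknown content is recovered when mixture mass lies off-signature", {
  sig <- makeSignature(K = 2L, G = 20L, seed = 5L)
  S <- as.matrix(sig)
  extra <- matrix(0.5e6 / 10, 10, 1,
                  dimnames = list(sprintf("unk%02d", 1:10), "s1"))
  b <- rbind(matrix(0.5 * S[, 1], ncol = 1,
                    dimnames = list(rownames(S), "s1")), extra)
  em <- ExpressionMatrix(b, "TPM")
  res <- clsDeconvolve(em, sig, allowUnknown = TRUE)
  expect_equal(as.matrix(res)["uncharacterized", 1], 0.5, tolerance = 1e-6)
  expect_equal(as.matrix(res)["ct1", 1], 0.5, tolerance = 1e-6)
  # oracle agreement on the same shared-gene problem
  f_oracle <- gridSearchCLS(S / 1e6, (b[rownames(S), 1] / 1e6),
                            step = 0.01, allowUnknown = TRUE)
  expect_lt(max(abs(as.matrix(res)[c("ct1", "ct2"), 1] - f_oracle[1:2])),
            0.02)
})

test_that("cls fractions are invariant to per-sample scaling", {
  sig <- makeSignature(K = 3L, G = 30L, seed = 9L)
  em <- mixtureFrom(sig, c(0.2, 0.5, 0.3))
  scaled <- ExpressionMatrix(as.matrix(em) * 37.5, "TPM")
  expect_equal(as.matrix(clsDeconvolve(em, sig)),
               as.matrix(clsDeconvolve(scaled, sig)), tolerance = 1e-9)
})

test_that("gene weights steer the cls fit and are validated", {
  sig <- makeSignature(K = 2L, G = 20L, seed = 12L)
  em <- mixtureFrom(sig, c(0.4, 0.6))
  w <- setNames(rep(1, 20), geneIds(sig))
  expect_equal(as.matrix(clsDeconvolve(em, sig, weights = w)),
               as.matrix(clsDeconvolve(em, sig)), tolerance = 1e-9)
  expect_error(clsDeconvolve(em, sig, weights = setNames(0 * w, names(w))),
               class = "murideconv_validation_error")
  expect_error(clsDeconvolve(em, sig, weights = unname(w)),
               class = "murideconv_validation_error")
})

test_that("a duplicated signature column triggers a degeneracy warning", {
  sig <- makeSignature(K = 2L, G = 20L, seed = 15L)
  v <- cbind(as.matrix(sig), ct3 = as.matrix(sig)[, 2])
  dup <- SignatureMatrix(v)
  em <- mixtureFrom(sig, c(0.5, 0.5))
  expect_warning(clsDeconvolve(em, dup), "duplicate")
})

test_that("nu-SVR recovers noiseless mixtures within 0.05", {
  sig <- makeSignature(K = 2L, G = 200L, seed = 31L)
  em <- mixtureFrom(sig, c(0.3, 0.7))
  f <- as.matrix(nusvrDeconvolve(em, sig))[, 1]
  expect_lt(max(abs(f - c(0.3, 0.7))), 0.05)
  # pure column
  em2 <- mixtureFrom(sig, c(1, 0))
  expect_gte(as.matrix(nusvrDeconvolve(em2, sig))["ct1", 1], 0.95)
  # single-candidate grid is the identity selection
  one <- as.matrix(nusvrDeconvolve(em, sig, nuGrid = 0.5))
  expect_equal(sum(one[, 1]), 1, tolerance = 1e-9)
  expect_error(nusvrDeconvolve(em, sig, nuGrid = numeric()),
               class = "murideconv_validation_error")
  expect_error(nusvrDeconvolve(em, sig, nuGrid = c(0.5, 1.5)),
               class = "murideconv_validation_error")
})

test_that("elastic net approximates fractions on noiseless mixtures", {
  sig <- makeSignature(K = 3L, G = 200L, seed = 41L)
  em <- mixtureFrom(sig, c(0.2, 0.3, 0.5))
  res <- elasticnetDeconvolve(em, sig, nRepeats = 1L, subsetFraction = 1,
                              seed = 4L)
  expect_identical(estimateType(res), "score")
  expect_lt(max(abs(as.matrix(res)[, 1] - c(0.2, 0.3, 0.5))), 0.05)
})

test_that("elastic net is bitwise reproducible under a fixed seed", {
  sig <- makeSignature(K = 3L, G = 60L, seed = 51L)
  em <- mixtureFrom(sig, c(0.1, 0.4, 0.5))
  r1 <- elasticnetDeconvolve(em, sig, nRepeats = 3L, seed = 7L)
  r2 <- elasticnetDeconvolve(em, sig, nRepeats = 3L, seed = 7L)
  expect_identical(as.matrix(r1), as.matrix(r2))
  r3 <- elasticnetDeconvolve(em, sig, nRepeats = 3L, seed = 8L)
  expect_false(identical(as.matrix(r1), as.matrix(r3)))
  # a subset below 2 genes is refused
  expect_error(elasticnetDeconvolve(em, sig, subsetFraction = 0.01,
                                    minGenes = 10L),
               class = "murideconv_validation_error")
})

test_that("runMethod dispatches transparently and validates names", {
  sig <- getResource("seqimmucc_like")
  S <- as.matrix(sig)
  B <- S %*% cbind(s1 = randomFractions(10, 61), s2 = randomFractions(10, 62))
  em <- ExpressionMatrix(B, "TPM")
  expect_error(runMethod(em, "bogus"), "registered methods")
  direct <- clsDeconvolve(em, sig)
  via <- runMethod(em, "cls")
  expect_equal(as.matrix(via), as.matrix(direct), tolerance = 1e-12)
  expect_identical(methodName(via), "cls")
  # marker engine dispatch equals the direct call
  mk <- getResource("mmcp_like")
  em_mk <- ExpressionMatrix(matrix(
    rlnorm(length(unique(unlist(lapply(geneSets(mk), names)))) * 2, 3, 1),
    ncol = 2, dimnames = list(unique(unlist(lapply(geneSets(mk), names))),
                              c("s1", "s2"))), "TPM")
  d <- suppressMessages(medianMarkerScore(em_mk, mk))
  v <- suppressMessages(runMethod(em_mk, "mmcp_like"))
  expect_equal(as.matrix(v), as.matrix(d), tolerance = 1e-12)
})

test_that("human-signature dispatch converts murine input first", {
  sig <- getResource("seqimmucc_like")
  S <- as.matrix(sig)
  B <- S %*% cbind(s1 = randomFractions(10, 71))
  em <- ExpressionMatrix(B, "TPM")            # murine symbols
  res <- suppressMessages(runMethod(em, "cls_human_sig", species = "mouse"))
  expect_s4_class(res, "DeconvolutionResult")
  expect_equal(sum(as.matrix(res)[, 1]), 1, tolerance = 1e-9)
  md <- resultMetadata(res)
  expect_true(md$ortholog_mapping$n_mapped > 0)
  # recovered fractions match the generating ones (case mapping is bijective
  # on these symbols)
  expect_equal(unname(as.matrix(res)[cellTypes(sig), 1]),
               unname(randomFractions(10, 71)), tolerance = 1e-6)
})
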