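# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# TPM-like random signature: K well-separated cell-type profiles over G
# genes, each column scaled to sum 1e6 (per-million contract).
makeSignature <- function(K = 3L, G = 30L, seed = 1L, separation = 50) {
  set.seed(seed)
  v <- matrix(runif(G * K, 1, 10), G, K)
  block <- split(seq_len(G), rep_len(seq_len(K), G))
  for (k in seq_len(K)) v[block[[k]], k] <- v[block[[k]], k] * separation
  dimnames(v) <- list(sprintf("g%03d", seq_len(G)), sprintf("ct%d", seq_len(K)))
  SignatureMatrix(sweep(v, 2, colSums(v), "/") * 1e6)
}

# random point on the K-simplex
randomFractions <- function(K, seed = 1L) {
  set.seed(seed)
  x <- rgamma(K, 1)
  x / sum(x)
}

mixtureFrom <- function(sig, f, sampleId = "s1") {
  S <- as.matrix(sig)
  b <- as.vector(S %*% f)
  ExpressionMatrix(matrix(b, ncol = 1, dimnames = list(rownames(S), sampleId)),
                   unit = "TPM")
}

# Brute-force simplex grid-search oracle for constrained least squares:
# enumerates all fraction vectors on a step-0.01 grid (optionally allowing
# sum <= 1) and returns the residual-minimizing one. Independent of the
# package solver: plain residual evaluation over an explicit grid.
gridSearchCLS <- function(S, b, step = 0.01, allowUnknown = FALSE) {
  K <- ncol(S)
  steps <- round(1 / step)
  grid <- expand.grid(rep(list(0:steps), K - 1L))
  rest <- steps - rowSums(grid)
  if (allowUnknown) keep <- rest >= 0 else keep <- TRUE
  grid <- grid[rest >= 0, , drop = FALSE]
  fmat <- as.matrix(cbind(grid, steps - rowSums(grid))) * step
  if (allowUnknown) {
    # last coordinate becomes free: enumerate it from 0 to the remainder
    base <- as.matrix(grid) * step
    fs <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
      rem <- 1 - sum(base[i, ])
      kk <- seq(0, rem + 1e-12, by = step)
      cbind(matrix(base[i, ], length(kk), K - 1L, byrow = TRUE), kk)
    }))
    fmat <- fs
  }
  resid <- colSums((S %*% t(fmat) - b)^2)
  fmat[which.min(resid), ]
}

# two-pass correlation oracle (naive covariance formula)
naiveCor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# write a small matrix TSV fixture on the fly
writeTSVFixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# the headline simulation protocol, computed once per test run
pseudobulkProtocol <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ref <- simulateSCReference(scSimParams(seed = 1L))
    pb <- suppressWarnings(simulatePseudobulk(ref$expr, ref$labels,
                                              nSamples = 20L,
                                              nCellsPerSample = 500L,
                                              seed = 1L))
    built <- buildSignatureFromSC(ref$expr, ref$labels,
                                  nMarkersPerType = 40L, minFold = 2)
    cache <<- list(ref = ref, pb = pb, built = built,
                   tpm = cpmNormalize(pb@expr),
                   truth = trueFractions(pb, "mrna"))
    cache
  }
})
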