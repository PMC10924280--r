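## Signature-matrix deconvolution engines. All three operate per sample on
## the gene intersection of mixture and signature. The mixture is
## per-million normalized over all its genes before restriction; the
## signature is trusted to be TPM-like on the same per-million scale, so
## mixture coefficients live on the fraction simplex.

.withSeed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.coverageError <- function(...) {
  stop(structure(class = c("murideconv_coverage_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1L))))
}

.sharedGenes <- function(expr, sig, minGenes = 10L, fatalBelow = 0.5,
                         warnBelow = 0.8) {
  shared <- intersect(rownames(expr@values), rownames(sig@values))
  frac <- length(shared) / nrow(sig@values)
  if (length(shared) < minGenes || frac < fatalBelow)
    .coverageError(
      "signature coverage too low: %d shared genes (%.0f%% of %d signature genes)",
      length(shared), 100 * frac, nrow(sig@values))
  if (frac < warnBelow)
    warning(sprintf("signature coverage %.0f%% (below %.0f%%)",
                    100 * frac, 100 * warnBelow))
  shared
}

# Mixture normalization: per-million over ALL genes of the matrix, then
# restriction to the shared genes (returned on the sum-1 scale). Normalizing
# before restricting is what lets unknown content surface: mixture mass
# sitting on genes outside the signature lowers the mixture's share on the
# signature genes, and the inequality constraint turns that shortfall into
# the "uncharacterized" fraction. Signature columns are NOT renormalized:
# they are TPM-like by contract (per-million over the reference
# transcriptome, possibly restricted to signature genes), so mixture and
# signature already share the per-million scale.
.mixtureRestrict <- function(m, rows) {
  cs <- colSums(m)
  if (any(cs <= 0))
    .validationError("a sample has zero total expression")
  sweep(m, 2L, cs, "/")[rows, , drop = FALSE]
}

#' Constrained least-squares deconvolution with unknown content
#'
#' Solves, per sample, `min_f || W^(1/2) (S f - b) ||^2` subject to
#' `f >= 0` and `sum(f) = 1` (or `sum(f) <= 1` when `allowUnknown = TRUE`,
#' in which case the shortfall `1 - sum(f)` is reported as an extra
#' `"uncharacterized"` row: the fraction of cells present in the mixture
#' but absent from the signature). The mixture is first re-normalized to a
#' per-million scale over all its genes and then restricted to the shared
#' genes; the signature is taken as TPM-like (per-million over the
#' reference transcriptome, possibly restricted to signature genes) and is
#' not rescaled. This makes the fit invariant to the overall scaling of
#' each sample, and it preserves the unknown-content signal: mixture mass
#' on genes outside the signature lowers the mixture's share on the
#' signature genes, and the inequality constraint reports the shortfall as
#' `"uncharacterized"`.
#'
#' The simplex constraint is imposed through an augmented row with weight
#' `1e4 x` the mean gene weight on top of a non-negative least-squares
#' solver, followed by an exact re-normalization of the solution; on
#' noiseless mixtures this recovers the generating fractions to well below
#' 1e-6.
#'
#' @param expr an [ExpressionMatrix-class] with unit `"TPM"`.
#' @param sig a [SignatureMatrix-class]. Gene intersection with `expr` must
#'   cover at least 10 genes and 50% of the signature.
#' @param allowUnknown estimate uncharacterized cellular content
#'   (inequality constraint) instead of forcing the known types to sum to 1.
#' @param mrnaRenormalize divide each known fraction by its cell type's
#'   mRNA scaling factor and re-normalize the known part (converts
#'   mRNA proportions to cell proportions).
#' @param weights optional non-negative per-gene weights, named by gene,
#'   covering the signature genes; not all zero.
#' @return A [DeconvolutionResult-class] with `estimateType = "fraction"`.
#' @examples
#' v <- matrix(c(9e5, 0, 1e5, 0, 8e5, 2e5), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("A", "B")))
#' sig <- SignatureMatrix(v)      # TPM-like: columns sum to 1e6
#' b <- v[, "A"] * 0.3 + v[, "B"] * 0.7
#' expr <- ExpressionMatrix(matrix(b, ncol = 1,
#'   dimnames = list(paste0("g", 1:3), "s1")), "TPM")
#' as.matrix(clsDeconvolve(expr, sig, minGenes = 3))
#' @param minGenes minimum shared-gene count (default 10).
#' @export
clsDeconvolve <- function(expr, sig, allowUnknown = FALSE,
                          mrnaRenormalize = FALSE, weights = NULL,
                          minGenes = 10L) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sig, "SignatureMatrix"))
  if (expr@unit != "TPM")
    .validationError("clsDeconvolve expects unit 'TPM', got '%s'", expr@unit)
  shared <- .sharedGenes(expr, sig, minGenes = minGenes)
  S <- sig@values[shared, , drop = FALSE] / 1e6     # to the sum-1 scale
  B <- .mixtureRestrict(expr@values, shared)
  K <- ncol(S)
  if (anyDuplicated(t(S)))
    warning("signature has duplicate cell-type columns; fit is degenerate")

  w <- rep(1, length(shared))
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(shared %in% names(weights)))
      .validationError("weights must be named and cover the signature genes")
    w <- weights[shared]
    if (any(w < 0) || all(w == 0))
      .validationError("weights must be non-negative and not all zero")
  }
  sw <- sqrt(w)

  A <- S * sw                              # row-scaled design
  if (allowUnknown) A <- cbind(A, uncharacterized = 0)
  lambda <- 1e4 * mean(w)                  # sum-constraint weight
  A <- rbind(A, sqrt(lambda))
  types <- colnames(sig@values)
  out_rows <- if (allowUnknown) c(types, "uncharacterized") else types
  out <- matrix(0, length(out_rows), ncol(B),
                dimnames = list(out_rows, colnames(B)))
  for (j in seq_len(ncol(B))) {
    y <- c(B[, j] * sw, sqrt(lambda))
    f <- pracma::lsqnonneg(A, y)$x
    if (sum(f) <= 0) {
      warning(sprintf("degenerate fit for sample '%s'; uniform fallback",
                      colnames(B)[j]))
      f <- rep(1 / length(f), length(f))
    }
    f <- f / sum(f)                        # exact simplex
    known <- f[seq_len(K)]
    unk <- if (allowUnknown) f[K + 1L] else 0
    if (mrnaRenormalize) {
      m <- sig@mrnaScaling[types]
      adj <- known / m
      if (sum(adj) > 0) known <- adj / sum(adj) * (1 - unk)
    }
    out[types, j] <- known
    if (allowUnknown) out["uncharacterized", j] <- unk
  }
  DeconvolutionResult(pmin(pmax(out, 0), 1), estimateType = "fraction",
                      methodName = "cls",
                      hasUnknownRow = allowUnknown,
                      metadata = list(allow_unknown = allowUnknown,
                                      mrna_renormalize = mrnaRenormalize))
}

#' nu-support-vector-regression deconvolution
#'
#' Per sample, the mixture and each signature column are z-scored over the
#' shared genes, a linear nu-SVR of the mixture on the signature columns is
#' fitted for each value of `nu` in `nuGrid` (regularization constant fixed
#' at `C = 1`), and the `nu` minimizing the root-mean-square deviation
#' between fitted and observed mixture is selected. Negative coefficients
#' are clipped to zero and the remainder normalized to sum to 1.
#'
#' @inheritParams clsDeconvolve
#' @param nuGrid candidate `nu` values in (0, 1); default
#'   `c(0.25, 0.5, 0.75)`.
#' @return A [DeconvolutionResult-class] with `estimateType = "fraction"`.
#' @export
nusvrDeconvolve <- function(expr, sig, nuGrid = c(0.25, 0.5, 0.75),
                            minGenes = 10L) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sig, "SignatureMatrix"))
  if (!length(nuGrid) || any(nuGrid <= 0) || any(nuGrid >= 1))
    .validationError("nuGrid must be a non-empty set of values in (0, 1)")
  shared <- .sharedGenes(expr, sig, minGenes = minGenes)
  S <- sig@values[shared, , drop = FALSE] / 1e6
  B <- .mixtureRestrict(expr@values, shared)
  Z <- scale(S)
  Z[, attr(Z, "scaled:scale") == 0] <- 0   # constant column guard
  types <- colnames(sig@values)
  out <- matrix(0, length(types), ncol(B),
                dimnames = list(types, colnames(B)))
  for (j in seq_len(ncol(B))) {
    y <- as.vector(scale(B[, j]))
    if (any(!is.finite(y))) y[!is.finite(y)] <- 0
    best <- NULL; best_rmse <- Inf
    for (nu in nuGrid) {
      fit <- e1071::svm(x = Z, y = y, type = "nu-regression",
                        kernel = "linear", nu = nu, cost = 1, scale = FALSE)
      rmse <- sqrt(mean((stats::fitted(fit) - y)^2))
      if (rmse < best_rmse) { best_rmse <- rmse; best <- fit }
    }
    co <- as.vector(t(best$coefs) %*% best$SV)
    co[co < 0] <- 0
    if (sum(co) <= 0) {
      warning(sprintf("all nu-SVR coefficients zero for sample '%s'; uniform fallback",
                      colnames(B)[j]))
      co <- rep(1, length(co))
    }
    out[, j] <- co / sum(co)
  }
  DeconvolutionResult(out, estimateType = "fraction", methodName = "nusvr",
                      metadata = list(nu_grid = nuGrid))
}

#' Elastic-net deconvolution (relative abundance scores)
#'
#' Digital-cell-quantification style engine: per sample, repeated
#' elastic-net regressions of the mixture on the signature columns, each on
#' a random subset of the shared genes, with coefficients averaged across
#' repeats. Coefficients may be negative and are reported as relative
#' abundance scores, not fractions; no clipping or re-normalization is
#' applied. The regularization path is chosen by internal cross-validation;
#' the gene subsets and fold assignments are drawn from `seed`, so runs are
#' reproducible.
#'
#' @inheritParams clsDeconvolve
#' @param l1Ratio elastic-net mixing parameter in `[0, 1]` (0 = ridge,
#'   1 = lasso); default 0.05, mostly-ridge as is customary for this engine
#'   family.
#' @param nRepeats number of random gene subsets averaged (default 10).
#' @param subsetFraction fraction of shared genes drawn per repeat
#'   (default 0.5).
#' @param seed integer seed for subset and fold randomness (default 0).
#' @return A [DeconvolutionResult-class] with `estimateType = "score"`.
#' @export
elasticnetDeconvolve <- function(expr, sig, l1Ratio = 0.05, nRepeats = 10L,
                                 subsetFraction = 0.5, seed = 0L,
                                 minGenes = 10L) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sig, "SignatureMatrix"))
  if (l1Ratio < 0 || l1Ratio > 1)
    .validationError("l1Ratio must be in [0, 1]")
  if (nRepeats < 1L) .validationError("nRepeats must be >= 1")
  if (subsetFraction <= 0 || subsetFraction > 1)
    .validationError("subsetFraction must be in (0, 1]")
  shared <- .sharedGenes(expr, sig, minGenes = minGenes)
  S <- sig@values[shared, , drop = FALSE]
  B <- .mixtureRestrict(expr@values, shared) * 1e6
  G <- length(shared)
  n_sub <- ceiling(subsetFraction * G)
  if (n_sub < 2L)
    .validationError("gene subsets too small (%d genes); increase subsetFraction",
                     n_sub)
  types <- colnames(sig@values)
  out <- matrix(0, length(types), ncol(B),
                dimnames = list(types, colnames(B)))
  .withSeed(seed, {
    for (j in seq_len(ncol(B))) {
      acc <- numeric(length(types))
      for (r in seq_len(nRepeats)) {
        idx <- sample.int(G, n_sub)
        x <- S[idx, , drop = FALSE]
        y <- B[idx, j]
        co <- .enFit(x, y, alpha = l1Ratio)
        acc <- acc + co
      }
      out[, j] <- acc / nRepeats
    }
  })
  DeconvolutionResult(out, estimateType = "score", methodName = "elasticnet",
                      metadata = list(l1_ratio = l1Ratio,
                                      n_repeats = nRepeats,
                                      subset_fraction = subsetFraction,
                                      seed = seed))
}

# one elastic-net fit; cross-validated lambda when enough observations
.enFit <- function(x, y, alpha) {
  if (nrow(x) >= 10L) {
    fit <- glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = 5L,
                             standardize = TRUE)
    as.vector(stats::coef(fit, s = "lambda.min"))[-1L]
  } else {
    fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = TRUE)
    as.vector(stats::coef(fit, s = min(fit$lambda)))[-1L]
  }
}
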