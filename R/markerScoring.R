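## Gene-set abundance scoring engines. Both return per-type scores that are
## comparable between samples for one cell type, but not across cell types
## within a sample (scores, not fractions).

.presentMarkers <- function(w, genes, ct, requireUp = TRUE) {
  keep <- names(w) %in% genes
  w <- w[keep]
  if (requireUp && !any(w == 1)) return(NULL)
  w
}

#' Median marker-gene abundance score
#'
#' For each cell type the score in a sample is the median expression of the
#' cell type's marker genes (weights must all be +1), optionally on the
#' `log2(TPM + 1)` scale (the default, matching common practice for
#' marker-median scoring). Markers absent from the matrix are ignored; a
#' cell type with no marker present yields an all-`NA` row and a warning.
#'
#' @param expr an [ExpressionMatrix-class] with unit `"TPM"`.
#' @param markers a [WeightedGeneSetCollection-class] with all weights +1.
#' @param logTransform use `log2(TPM + 1)` (default `TRUE`); `FALSE` scores
#'   raw TPM.
#' @return A [DeconvolutionResult-class] with `estimateType = "score"`.
#' @examples
#' m <- matrix(c(1, 3, 100, 2, 2, 2), ncol = 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' sets <- WeightedGeneSetCollection(list(T = c("g1", "g2", "g3")))
#' as.matrix(medianMarkerScore(ExpressionMatrix(m, "TPM"), sets,
#'                             logTransform = FALSE))
#' @export
medianMarkerScore <- function(expr, markers, logTransform = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"),
            is(markers, "WeightedGeneSetCollection"))
  if (expr@unit != "TPM")
    .validationError("medianMarkerScore expects unit 'TPM', got '%s'",
                     expr@unit)
  if (any(vapply(markers@sets, function(w) any(w == -1), logical(1))))
    .validationError("medianMarkerScore accepts only +1 (up) markers")

  x <- expr@values
  if (logTransform) x <- log2(x + 1)
  types <- names(markers@sets)
  out <- matrix(NA_real_, length(types), ncol(x),
                dimnames = list(types, colnames(x)))
  n_empty <- 0L
  for (ct in types) {
    present <- intersect(names(markers@sets[[ct]]), rownames(x))
    if (!length(present)) { n_empty <- n_empty + 1L; next }
    if (length(present) < length(markers@sets[[ct]]))
      message(sprintf("'%s': %d of %d markers absent from matrix", ct,
                      length(markers@sets[[ct]]) - length(present),
                      length(markers@sets[[ct]])))
    out[ct, ] <- apply(x[present, , drop = FALSE], 2L, median)
  }
  if (n_empty == length(types))
    .validationError("no cell type has any marker present in the matrix")
  if (n_empty > 0L)
    warning(sprintf("%d cell type(s) have no marker present; rows are NA",
                    n_empty))
  DeconvolutionResult(out, estimateType = "score",
                      methodName = "mmcp_like",
                      metadata = list(log_transform = logTransform))
}

#' Signed normalized-rank abundance score
#'
#' Rank-based gene-set scoring in the style of sorted-expression association
#' methods. Per sample, all genes are ranked ascending by expression
#' (mid-ranks for ties) and ranks normalized to `(0, 1]` by the gene count.
#' The score of a cell type is the mean normalized rank of its up markers
#' minus the mean normalized rank of its down markers; without down markers
#' the up mean is centered at 0.5 (its null expectation up to `O(1/G)`), so
#' a random gene set scores 0 in expectation. Being rank-based, the score
#' is invariant under any strictly monotone transform of a sample's
#' expression vector, so the unit tag is not restricted.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param sets a [WeightedGeneSetCollection-class]; weights -1 mark down
#'   genes.
#' @return A [DeconvolutionResult-class] with `estimateType = "score"`,
#'   scores in `[-1, 1]`.
#' @export
signedRankScore <- function(expr, sets) {
  stopifnot(is(expr, "ExpressionMatrix"),
            is(sets, "WeightedGeneSetCollection"))
  x <- expr@values
  G <- nrow(x)
  r <- apply(x, 2L, rank, ties.method = "average") / G   # (0, 1], mid-ranks
  rownames(r) <- rownames(x)
  types <- names(sets@sets)
  out <- matrix(NA_real_, length(types), ncol(x),
                dimnames = list(types, colnames(x)))
  n_empty <- 0L
  for (ct in types) {
    w <- sets@sets[[ct]]
    up <- intersect(names(w)[w == 1], rownames(x))
    down <- intersect(names(w)[w == -1], rownames(x))
    if (!length(up)) { n_empty <- n_empty + 1L; next }
    up_mean <- colMeans(r[up, , drop = FALSE])
    out[ct, ] <- if (length(down))
      up_mean - colMeans(r[down, , drop = FALSE])
    else up_mean - 0.5
  }
  if (n_empty == length(types))
    .validationError("no cell type has any up marker present in the matrix")
  if (n_empty > 0L)
    warning(sprintf("%d cell type(s) have no up marker present; rows are NA",
                    n_empty))
  DeconvolutionResult(out, estimateType = "score", methodName = "base_like")
}
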