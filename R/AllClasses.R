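#' @import methods
#' @importFrom stats median cor rnbinom rpois rlnorm rmultinom runif rgamma sd quantile setNames
#' @importFrom utils read.delim write.table head
NULL

.EXPR_UNITS <- c("TPM", "counts", "log2_TPM")

#' ExpressionMatrix: genes-by-samples bulk or single-cell expression
#'
#' A dense non-negative expression matrix with unique gene symbols as row
#' names, unique sample (or cell) identifiers as column names, and a declared
#' unit. Units are never guessed from the data: log-scale input must be
#' declared as `"log2_TPM"` by the caller.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot unit one of `"TPM"`, `"counts"`, `"log2_TPM"`.
#'
#' @seealso [ExpressionMatrix()], [readExpression()]
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (nrow(v) == 0L || ncol(v) == 0L) msgs <- c(msgs, "matrix is empty")
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msgs <- c(msgs, sprintf("unit must be one of %s",
                            paste(.EXPR_UNITS, collapse = ", ")))
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "gene ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "sample ids must be present and unique")
  if (any(!is.finite(v))) msgs <- c(msgs, "values must be finite")
  if (length(object@unit) == 1L && object@unit %in% c("TPM", "counts") &&
      any(v < 0))
    msgs <- c(msgs, sprintf("negative values are invalid for unit '%s'",
                            object@unit))
  if (length(object@unit) == 1L && object@unit == "TPM" &&
      nrow(v) > 0L && any(colSums(v) <= 0))
    msgs <- c(msgs, "TPM matrix has an all-zero sample column")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param unit `"TPM"`, `"counts"` or `"log2_TPM"`.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("Cd8a", "Cd4", "Ms4a1"),
#'                                            c("s1", "s2")))
#' ExpressionMatrix(m, unit = "counts")
#' @export
ExpressionMatrix <- function(values, unit = c("TPM", "counts", "log2_TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, unit = unit)
}

#' SignatureMatrix: genes-by-cell-types expected expression profiles
#'
#' The mixing basis for regression-based deconvolution: one column of
#' TPM-like expected expression per cell type, optionally with a per-type
#' mRNA scaling factor (total mRNA content multiplier) used to convert
#' mRNA-proportion estimates into cell-proportion estimates.
#'
#' @slot values non-negative numeric matrix, genes x cell types.
#' @slot mrnaScaling named positive numeric, one value per cell type.
#'
#' @seealso [SignatureMatrix()], [readSignature()], [clsDeconvolve()]
#' @export
setClass("SignatureMatrix",
  representation(values = "matrix", mrnaScaling = "numeric"))

setValidity("SignatureMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) == 0L || ncol(v) == 0L) msgs <- c(msgs, "matrix is empty")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "gene ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "cell-type labels must be present and unique")
  if (any(!is.finite(v)) || any(v < 0))
    msgs <- c(msgs, "signature values must be finite and non-negative")
  if (ncol(v) > 0L && any(apply(v, 2L, max) <= 0))
    msgs <- c(msgs, "every cell-type column needs at least one positive entry")
  ms <- object@mrnaScaling
  if (length(ms) != ncol(v) || !identical(names(ms), colnames(v)) ||
      any(!is.finite(ms)) || any(ms <= 0))
    msgs <- c(msgs, "mrnaScaling must hold one strictly positive value per cell type")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignatureMatrix
#'
#' @param values non-negative numeric matrix, gene row names, cell-type
#'   column names.
#' @param mrnaScaling optional positive numeric vector, one value per cell
#'   type (default all 1: no mRNA-content correction).
#' @return A validated [SignatureMatrix-class] object.
#' @export
SignatureMatrix <- function(values, mrnaScaling = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mrnaScaling))
    mrnaScaling <- setNames(rep(1, ncol(values)), colnames(values))
  if (is.null(names(mrnaScaling)))
    names(mrnaScaling) <- colnames(values)
  mrnaScaling <- mrnaScaling[colnames(values)]
  new("SignatureMatrix", values = values, mrnaScaling = mrnaScaling)
}

#' WeightedGeneSetCollection: signed marker gene sets per cell type
#'
#' One entry per cell type: a named numeric vector of marker genes with
#' weights +1 (up marker) or -1 (down marker). Plain marker sets have all
#' weights +1.
#'
#' @slot sets named list; each element a named numeric vector of +1/-1
#'   weights, names are gene symbols.
#'
#' @seealso [WeightedGeneSetCollection()], [readGMT()],
#'   [medianMarkerScore()], [signedRankScore()]
#' @export
setClass("WeightedGeneSetCollection", representation(sets = "list"))

setValidity("WeightedGeneSetCollection", function(object) {
  s <- object@sets
  msgs <- character()
  if (length(s) == 0L) msgs <- c(msgs, "collection is empty")
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    msgs <- c(msgs, "cell-type names must be present and unique")
  for (ct in names(s)) {
    w <- s[[ct]]
    if (!is.numeric(w) || is.null(names(w)) || any(!nzchar(names(w))))
      msgs <- c(msgs, sprintf("'%s': weights must be a named numeric vector", ct))
    else {
      if (anyDuplicated(names(w)))
        msgs <- c(msgs, sprintf("'%s': duplicate gene in set", ct))
      if (!all(w %in% c(1, -1)))
        msgs <- c(msgs, sprintf("'%s': weights must be +1 or -1", ct))
      if (!any(w == 1))
        msgs <- c(msgs, sprintf("'%s': needs at least one +1 gene", ct))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a WeightedGeneSetCollection
#'
#' @param sets named list of named numeric weight vectors (+1/-1), or of
#'   plain character gene vectors (interpreted as all +1).
#' @return A validated [WeightedGeneSetCollection-class] object.
#' @examples
#' WeightedGeneSetCollection(list(
#'   `T cell` = c(Cd3e = 1, Cd3d = 1),
#'   `NK cell` = c(Ncr1 = 1, Cd3e = -1)))
#' @export
WeightedGeneSetCollection <- function(sets) {
  sets <- lapply(sets, function(x) {
    if (is.character(x)) setNames(rep(1, length(x)), x) else x
  })
  new("WeightedGeneSetCollection", sets = sets)
}

#' DeconvolutionResult: cell-type estimates per sample
#'
#' Estimates are either `"fraction"` (on the simplex; comparable within and
#' between samples) or `"score"` (arbitrary per-type scale; comparable
#' between samples only). Fraction results may carry an extra
#' `"uncharacterized"` row holding the estimated unknown cellular content.
#'
#' @slot values numeric matrix, cell types x samples.
#' @slot estimateType `"fraction"` or `"score"`.
#' @slot methodName engine that produced the estimates.
#' @slot hasUnknownRow logical; `TRUE` when a row named `"uncharacterized"`
#'   holds unknown content.
#' @slot metadata list of provenance (seed, options, notes).
#'
#' @seealso [DeconvolutionResult()], [writeResult()], [runMethod()]
#' @export
setClass("DeconvolutionResult",
  representation(values = "matrix", estimateType = "character",
                 methodName = "character", hasUnknownRow = "logical",
                 metadata = "list"))

setValidity("DeconvolutionResult", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "cell-type labels must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "sample ids must be present and unique")
  if (length(object@estimateType) != 1L ||
      !object@estimateType %in% c("fraction", "score"))
    msgs <- c(msgs, "estimateType must be 'fraction' or 'score'")
  if (isTRUE(object@hasUnknownRow) && !"uncharacterized" %in% rownames(v))
    msgs <- c(msgs, "hasUnknownRow is TRUE but no 'uncharacterized' row")
  if (identical(object@estimateType, "fraction")) {
    ok <- v[is.finite(v)]
    if (any(ok < -1e-9) || any(ok > 1 + 1e-9))
      msgs <- c(msgs, "fraction estimates must lie in [0, 1]")
    cs <- colSums(v)
    cs <- cs[is.finite(cs)]
    if (isTRUE(object@hasUnknownRow)) {
      if (any(abs(cs - 1) > 1e-9))
        msgs <- c(msgs, "with an uncharacterized row, columns must sum to 1")
    } else if (any(cs > 1 + 1e-9)) {
      msgs <- c(msgs, "fraction columns must sum to at most 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DeconvolutionResult
#'
#' @param values numeric matrix, cell types in rows, samples in columns.
#' @param estimateType `"fraction"` or `"score"`.
#' @param methodName character scalar naming the producing engine.
#' @param hasUnknownRow logical; see [DeconvolutionResult-class].
#' @param metadata list of provenance entries.
#' @return A validated [DeconvolutionResult-class] object.
#' @export
DeconvolutionResult <- function(values, estimateType, methodName = "unknown",
                                hasUnknownRow = FALSE, metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("DeconvolutionResult", values = values, estimateType = estimateType,
      methodName = methodName, hasUnknownRow = hasUnknownRow,
      metadata = metadata)
}

#' GeneMappingTable: cross-species gene symbol pairs
#'
#' @slot pairs data.frame with character columns `source` and `target`.
#' @slot provenance free-text origin of the table.
#' @seealso [loadMappingTable()], [caseConventionFallback()],
#'   [convertExpression()]
#' @export
setClass("GeneMappingTable",
  representation(pairs = "data.frame", provenance = "character"))

setValidity("GeneMappingTable", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!identical(colnames(p), c("source", "target")))
    msgs <- c(msgs, "pairs must have columns 'source' and 'target'")
  else {
    if (anyDuplicated(p))
      msgs <- c(msgs, "exact duplicate (source, target) pairs are invalid")
    bad <- !nzchar(p$source) | !nzchar(p$target) |
      grepl("\\s", p$source) | grepl("\\s", p$target)
    if (any(bad))
      msgs <- c(msgs, "symbols must be non-empty and whitespace-free")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneMappingTable
#'
#' @param source,target character vectors of equal length (source species
#'   symbol, target species symbol).
#' @param provenance free-text origin string.
#' @return A validated [GeneMappingTable-class] object.
#' @export
GeneMappingTable <- function(source, target, provenance = "user") {
  pairs <- data.frame(source = as.character(source),
                      target = as.character(target),
                      stringsAsFactors = FALSE)
  new("GeneMappingTable", pairs = pairs, provenance = provenance)
}

#' CellTypeOntology: nomenclature harmonization and fine-to-major hierarchy
#'
#' @slot harmonization data.frame with columns `method`, `raw`, `canonical`.
#' @slot hierarchy named character vector mapping each fine-grained label to
#'   exactly one major label.
#' @slot majorRoster ordered character vector of major cell-type labels.
#' @seealso [harmonizeResult()], [groupToMajor()], [defaultOntology()]
#' @export
setClass("CellTypeOntology",
  representation(harmonization = "data.frame", hierarchy = "character",
                 majorRoster = "character"))

setValidity("CellTypeOntology", function(object) {
  msgs <- character()
  h <- object@harmonization
  if (!identical(colnames(h), c("method", "raw", "canonical")))
    msgs <- c(msgs, "harmonization needs columns method, raw, canonical")
  hier <- object@hierarchy
  if (length(hier) && (is.null(names(hier)) || anyDuplicated(names(hier))))
    msgs <- c(msgs, "hierarchy must map each fine label to exactly one major label")
  if (length(hier) && !all(unique(hier) %in% object@majorRoster))
    msgs <- c(msgs, "every major label in the hierarchy must be in majorRoster")
  if (anyDuplicated(object@majorRoster))
    msgs <- c(msgs, "majorRoster labels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' PseudoBulkDataset: simulated bulk samples with known composition
#'
#' @slot expr simulated counts [ExpressionMatrix-class], genes x samples.
#' @slot trueFractionsCells cell-type x sample matrix of realized cell-count
#'   fractions (columns sum to 1).
#' @slot trueFractionsMrna same shape, fractions weighted by per-type mRNA
#'   content (mRNA bias x mean library size), columns sum to 1.
#' @slot params full simulation parameters and seed, for provenance.
#' @seealso [simulatePseudobulk()]
#' @export
setClass("PseudoBulkDataset",
  representation(expr = "ExpressionMatrix", trueFractionsCells = "matrix",
                 trueFractionsMrna = "matrix", params = "list"))

setValidity("PseudoBulkDataset", function(object) {
  msgs <- character()
  for (nm in c("trueFractionsCells", "trueFractionsMrna")) {
    m <- slot(object, nm)
    if (any(abs(colSums(m) - 1) > 1e-9))
      msgs <- c(msgs, sprintf("%s columns must sum to 1", nm))
    if (!identical(colnames(m), colnames(object@expr@values)))
      msgs <- c(msgs, sprintf("%s sample ids must match expr", nm))
  }
  if (length(msgs)) msgs else TRUE
})
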