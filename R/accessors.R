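#' Accessors for murideconv containers
#'
#' Small accessor functions used throughout the package instead of direct
#' slot access: gene and sample identifiers, cell-type labels, unit tags,
#' estimate types, and the underlying matrices via `as.matrix`.
#'
#' @param x a murideconv container object.
#' @param flavor for `trueFractions`, which ground truth to return:
#'   `"mrna"` (mRNA-weighted, what un-normalized regression engines recover)
#'   or `"cells"` (plain cell-count fractions).
#' @param ... ignored.
#' @return The corresponding slot content (character vectors, numeric
#'   vectors, matrices, or lists; see each container's class page).
#' @name accessors
NULL

#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("geneIds", "SignatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("sampleIds", "DeconvolutionResult", function(x) colnames(x@values))
#' @rdname accessors
setMethod("cellTypes", "SignatureMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("cellTypes", "DeconvolutionResult", function(x) rownames(x@values))
#' @rdname accessors
setMethod("cellTypes", "WeightedGeneSetCollection", function(x) names(x@sets))
#' @rdname accessors
setMethod("exprUnit", "ExpressionMatrix", function(x) x@unit)
#' @rdname accessors
setMethod("mrnaScaling", "SignatureMatrix", function(x) x@mrnaScaling)
#' @rdname accessors
setMethod("geneSets", "WeightedGeneSetCollection", function(x) x@sets)
#' @rdname accessors
setMethod("estimateType", "DeconvolutionResult", function(x) x@estimateType)
#' @rdname accessors
setMethod("methodName", "DeconvolutionResult", function(x) x@methodName)
#' @rdname accessors
setMethod("resultMetadata", "DeconvolutionResult", function(x) x@metadata)
#' @rdname accessors
setMethod("mappingPairs", "GeneMappingTable", function(x) x@pairs)
#' @rdname accessors
setMethod("majorRoster", "CellTypeOntology", function(x) x@majorRoster)
#' @rdname accessors
setMethod("hierarchyMap", "CellTypeOntology", function(x) x@hierarchy)
#' @rdname accessors
setMethod("trueFractions", "PseudoBulkDataset",
  function(x, flavor = c("mrna", "cells")) {
    flavor <- match.arg(flavor)
    if (flavor == "mrna") x@trueFractionsMrna else x@trueFractionsCells
  })

#' @rdname accessors
#' @export
setMethod("as.matrix", "ExpressionMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("as.matrix", "SignatureMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("as.matrix", "DeconvolutionResult", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))
#' @rdname accessors
#' @export
setMethod("dim", "SignatureMatrix", function(x) dim(x@values))
#' @rdname accessors
#' @export
setMethod("dim", "DeconvolutionResult", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [unit: %s]\n",
              nrow(object@values), ncol(object@values), object@unit))
  cat("  genes:  ", .preview(rownames(object@values)), "\n")
  cat("  samples:", .preview(colnames(object@values)), "\n")
})

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf("SignatureMatrix: %d genes x %d cell types\n",
              nrow(object@values), ncol(object@values)))
  cat("  cell types:", .preview(colnames(object@values)), "\n")
  if (any(object@mrnaScaling != 1))
    cat("  mRNA scaling factors present\n")
})

setMethod("show", "WeightedGeneSetCollection", function(object) {
  ns <- vapply(object@sets, length, integer(1))
  cat(sprintf("WeightedGeneSetCollection: %d cell types, %d genes total\n",
              length(object@sets), sum(ns)))
  cat("  cell types:", .preview(names(object@sets)), "\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult [%s]: %d cell types x %d samples (%s)\n",
              object@methodName, nrow(object@values), ncol(object@values),
              object@estimateType))
  if (isTRUE(object@hasUnknownRow))
    cat("  includes 'uncharacterized' (unknown content) row\n")
})

setMethod("show", "GeneMappingTable", function(object) {
  cat(sprintf("GeneMappingTable: %d pairs [%s]\n",
              nrow(object@pairs), object@provenance))
})

setMethod("show", "CellTypeOntology", function(object) {
  cat(sprintf(
    "CellTypeOntology: %d harmonization entries, %d fine labels, %d major types\n",
    nrow(object@harmonization), length(object@hierarchy),
    length(object@majorRoster)))
})

setMethod("show", "PseudoBulkDataset", function(object) {
  cat(sprintf("PseudoBulkDataset: %d genes x %d samples, %d cell types\n",
              nrow(object@expr@values), ncol(object@expr@values),
              nrow(object@trueFractionsCells)))
  cat("  ground truth: cell fractions + mRNA-weighted fractions\n")
})

.preview <- function(x, n = 4L) {
  if (length(x) <= n) return(paste(x, collapse = ", "))
  paste0(paste(head(x, n), collapse = ", "), ", ... (", length(x), ")")
}
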