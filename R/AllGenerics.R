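#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))
#' @rdname accessors
#' @export
setGeneric("mrnaScaling", function(x) standardGeneric("mrnaScaling"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("estimateType", function(x) standardGeneric("estimateType"))
#' @rdname accessors
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))
#' @rdname accessors
#' @export
setGeneric("resultMetadata", function(x) standardGeneric("resultMetadata"))
#' @rdname accessors
#' @export
setGeneric("mappingPairs", function(x) standardGeneric("mappingPairs"))
#' @rdname accessors
#' @export
setGeneric("trueFractions", function(x, flavor = c("mrna", "cells"))
  standardGeneric("trueFractions"))
#' @rdname accessors
#' @export
setGeneric("majorRoster", function(x) standardGeneric("majorRoster"))
#' @rdname accessors
#' @export
setGeneric("hierarchyMap", function(x) standardGeneric("hierarchyMap"))
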