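## Unified dispatch over the deconvolution engines: one entry point, one
## nomenclature. Human-signature methods on murine input are routed through
## the ortholog mapper first.

.methodTable <- function() {
  c(mmcp_like = "median marker score on the bundled 14-type marker sets",
    base_like = "signed normalized-rank score on marker gene sets",
    cls = "constrained least squares on a murine signature (fractions)",
    nusvr = "linear nu-SVR on a murine signature (fractions)",
    elasticnet = "repeated-subset elastic net on a murine signature (scores)",
    cls_human_sig = "constrained least squares on a human-space signature; murine input is ortholog-mapped first")
}

#' List the registered deconvolution methods
#'
#' @return Named character vector: method name -> one-line description.
#' @export
registeredMethods <- function() .methodTable()

#' Run a registered deconvolution method
#'
#' The single entry point over all engines. Resources default to the
#' bundled ones (marker sets for the scoring engines, the bundled murine
#' signature for the regression engines) and can be overridden. For
#' `"cls_human_sig"` with `species = "mouse"`, the expression matrix is
#' first converted to human gene space via `orthologTable` (default: the
#' symbol-case convention over the input genes); the mapping report is
#' recorded in the result metadata. Output labels are passed through the
#' ontology harmonization unless `harmonizeLabels = FALSE`.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param method one of [registeredMethods()].
#' @param signature optional [SignatureMatrix-class] override for the
#'   regression engines.
#' @param markers optional [WeightedGeneSetCollection-class] override for
#'   the scoring engines.
#' @param species species of `expr`: `"mouse"` or `"human"`; drives the
#'   ortholog conversion for human-signature methods.
#' @param orthologTable optional [GeneMappingTable-class] used for the
#'   conversion.
#' @param ontology [CellTypeOntology-class] for label harmonization.
#' @param harmonizeLabels harmonize output labels (default `TRUE`).
#' @param ... passed to the selected engine (e.g. `allowUnknown`, `seed`,
#'   `nuGrid`, `logTransform`).
#' @return A [DeconvolutionResult-class].
#' @examples
#' sig <- getResource("seqimmucc_like")
#' m <- as.matrix(sig)[, "B cell", drop = FALSE] %*% matrix(1, 1, 2)
#' dimnames(m) <- list(geneIds(sig), c("s1", "s2"))
#' expr <- ExpressionMatrix(m, "TPM")
#' runMethod(expr, "cls")
#' @export
runMethod <- function(expr, method, signature = NULL, markers = NULL,
                      species = c("mouse", "human"), orthologTable = NULL,
                      ontology = defaultOntology(), harmonizeLabels = TRUE,
                      ...) {
  species <- match.arg(species)
  known <- names(.methodTable())
  if (!method %in% known)
    stop(sprintf("unknown method '%s'; registered methods: %s",
                 method, paste(known, collapse = ", ")))
  conv_report <- NULL
  res <- switch(method,
    mmcp_like = {
      if (is.null(markers)) markers <- getResource("mmcp_like")
      medianMarkerScore(expr, markers, ...)
    },
    base_like = {
      if (is.null(markers)) markers <- getResource("mmcp_like")
      signedRankScore(expr, markers)
    },
    cls = {
      if (is.null(signature)) signature <- getResource("seqimmucc_like")
      clsDeconvolve(expr, signature, ...)
    },
    nusvr = {
      if (is.null(signature)) signature <- getResource("seqimmucc_like")
      nusvrDeconvolve(expr, signature, ...)
    },
    elasticnet = {
      if (is.null(signature)) signature <- getResource("seqimmucc_like")
      elasticnetDeconvolve(expr, signature, ...)
    },
    cls_human_sig = {
      if (is.null(signature)) {
        signature <- getResource("seqimmucc_like")
        hs <- as.matrix(signature)
        rownames(hs) <- toupper(rownames(hs))   # human-space stand-in
        signature <- SignatureMatrix(hs, mrnaScaling = mrnaScaling(signature))
      }
      if (species == "mouse") {
        if (is.null(orthologTable))
          orthologTable <- caseConventionFallback(geneIds(expr))
        conv <- convertExpression(expr, orthologTable)
        conv_report <- conv$report
        message(sprintf("ortholog conversion: %d/%d genes mapped [%s]",
                        conv$report$n_mapped, conv$report$n_source_genes,
                        conv$report$provenance))
        expr <- conv$expr
      }
      clsDeconvolve(expr, signature, ...)
    })
  res@methodName <- method
  if (!is.null(conv_report))
    res@metadata$ortholog_mapping <- conv_report[
      c("n_source_genes", "n_mapped", "n_dropped", "policies", "provenance")]
  if (harmonizeLabels) res <- harmonizeResult(res, ontology)
  validObject(res)
  res
}
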