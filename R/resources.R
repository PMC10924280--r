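## Bundled murine resources. The marker collection, signature matrix,
## fine-grained phenotype roster and ortholog table shipped here are compact
## curated stand-ins with realistic structure (cell-type cardinalities,
## marker-gene style, label hierarchy); they are suited to examples, tests
## and method development, not a replacement for study-specific resources.

.resourceRegistry <- function() {
  list(
    mmcp_like = list(
      kind = "marker_collection",
      file = "mmcp_like.gmt",
      species = "mouse",
      n_cell_types = 14L,
      description = "median-marker scoring sets for 14 immune and stromal cell types"),
    seqimmucc_like = list(
      kind = "signature_matrix",
      file = "seqimmucc_like_signature.tsv",
      species = "mouse",
      n_cell_types = 10L,
      description = "deconvolution signature matrix for 10 immune cell types"),
    finegrained_like = list(
      kind = "phenotype_roster",
      file = "celltype_hierarchy.tsv",
      species = "mouse",
      n_cell_types = 19L,
      description = "fine-grained immune phenotype roster mapped to 19 major types"))
}

#' List bundled resources
#'
#' @return A data.frame with one row per bundled resource: name, kind,
#'   species, number of cell types, description.
#' @export
listResources <- function() {
  reg <- .resourceRegistry()
  data.frame(name = names(reg),
             kind = vapply(reg, `[[`, "", "kind"),
             species = vapply(reg, `[[`, "", "species"),
             n_cell_types = vapply(reg, `[[`, 0L, "n_cell_types"),
             description = vapply(reg, `[[`, "", "description"),
             row.names = NULL)
}

#' Fetch a bundled resource by name
#'
#' @param name one of the names in [listResources()].
#' @return A [WeightedGeneSetCollection-class] (`"mmcp_like"`), a
#'   [SignatureMatrix-class] (`"seqimmucc_like"`), or a data.frame with
#'   columns `fine`, `major` (`"finegrained_like"`).
#' @examples
#' cellTypes(getResource("mmcp_like"))
#' @export
getResource <- function(name) {
  reg <- .resourceRegistry()
  if (!name %in% names(reg)) {
    d <- utils::adist(name, names(reg))
    stop(sprintf("unknown resource '%s'; did you mean '%s'? (available: %s)",
                 name, names(reg)[which.min(d)],
                 paste(names(reg), collapse = ", ")))
  }
  path <- system.file("extdata", reg[[name]]$file, package = "murideconv",
                      mustWork = TRUE)
  switch(reg[[name]]$kind,
    marker_collection = readGMT(path),
    signature_matrix  = readSignature(path),
    phenotype_roster  = {
      df <- read.delim(path, stringsAsFactors = FALSE)
      df[df$fine != df$major, c("fine", "major")]
    })
}

#' Build a signature matrix and marker sets from labeled single-cell counts
#'
#' Each cell type's signature column is its mean CPM across cells (CPM, not
#' TPM: gene length is unavailable from count matrices). Markers for a type
#' are the top `nMarkersPerType` genes ranked by the fold-change of the
#' type's mean over the *maximum* mean across all other types (stricter
#' than fold over the mean of others: a gene shared by two types cannot be
#' a marker of either), requiring fold >= `minFold`. The returned signature
#' is restricted to the union of selected markers. Fold ties are broken by
#' lexicographic gene symbol, so the builder is deterministic given
#' identical input ordering.
#'
#' @param scCounts an [ExpressionMatrix-class] with unit `"counts"`, cells
#'   as columns.
#' @param labels named character vector mapping each cell id to its cell
#'   type; must cover all columns of `scCounts`.
#' @param nMarkersPerType markers selected per type (default 20).
#' @param minFold minimum specificity fold-change (default 2).
#' @return A list with `signature` ([SignatureMatrix-class]) and `markers`
#'   ([WeightedGeneSetCollection-class]).
#' @export
buildSignatureFromSC <- function(scCounts, labels, nMarkersPerType = 20L,
                                 minFold = 2) {
  stopifnot(is(scCounts, "ExpressionMatrix"))
  if (scCounts@unit != "counts")
    .validationError("buildSignatureFromSC expects unit 'counts'")
  cells <- colnames(scCounts@values)
  if (!all(cells %in% names(labels)))
    .validationError("labels must cover every cell in the count matrix")
  labels <- labels[cells]
  types <- sort(unique(labels))
  if (length(types) < 2L)
    .validationError("need at least 2 cell types, got %d", length(types))
  n_per <- table(labels)
  small <- names(n_per)[n_per < 10L]
  if (length(small))
    .validationError("cell type(s) with fewer than 10 cells: %s",
                     paste(small, collapse = ", "))

  cpm <- sweep(scCounts@values, 2L, colSums(scCounts@values), "/") * 1e6
  M <- vapply(types, function(t) rowMeans(cpm[, labels == t, drop = FALSE]),
              numeric(nrow(cpm)))
  colnames(M) <- types

  sets <- list()
  for (t in types) {
    others <- apply(M[, colnames(M) != t, drop = FALSE], 1L, max)
    fold <- ifelse(M[, t] > 0 & others == 0, Inf, M[, t] / others)
    fold[!is.finite(fold) & !(M[, t] > 0 & others == 0)] <- 0   # 0/0
    pass <- if (is.finite(minFold)) which(fold >= minFold) else integer()
    if (!length(pass))
      .validationError("no gene reaches fold %.3g for cell type '%s'",
                       minFold, t)
    g <- rownames(M)[pass]
    ord <- order(-fold[pass], g)                 # ties: lexicographic symbol
    sets[[t]] <- setNames(rep(1, min(nMarkersPerType, length(pass))),
                          g[ord][seq_len(min(nMarkersPerType, length(pass)))])
  }
  marker_union <- sort(unique(unlist(lapply(sets, names))))
  list(signature = SignatureMatrix(M[marker_union, , drop = FALSE]),
       markers = WeightedGeneSetCollection(sets))
}

#' Report how well a signature's genes are covered by an expression matrix
#'
#' @param sigOrSets a [SignatureMatrix-class] or
#'   [WeightedGeneSetCollection-class].
#' @param expr an [ExpressionMatrix-class].
#' @param warnBelow overall-coverage warning threshold (default 0.8).
#' @return A list: `per_type` (named coverage fractions), `overall`, and
#'   `warning` (logical flag; also emitted as an R warning).
#' @export
validateSignatureCoverage <- function(sigOrSets, expr, warnBelow = 0.8) {
  stopifnot(is(expr, "ExpressionMatrix"))
  genes <- rownames(expr@values)
  if (is(sigOrSets, "SignatureMatrix")) {
    per_type_genes <- lapply(colnames(sigOrSets@values),
                             function(ct) rownames(sigOrSets@values))
    names(per_type_genes) <- colnames(sigOrSets@values)
    all_genes <- rownames(sigOrSets@values)
  } else if (is(sigOrSets, "WeightedGeneSetCollection")) {
    per_type_genes <- lapply(sigOrSets@sets, names)
    all_genes <- unique(unlist(per_type_genes))
  } else .validationError("unsupported resource type for coverage check")
  per_type <- vapply(per_type_genes,
                     function(g) mean(g %in% genes), numeric(1))
  overall <- mean(all_genes %in% genes)
  warn <- overall < warnBelow
  if (warn)
    warning(sprintf("only %.0f%% of resource genes present in the matrix",
                    100 * overall))
  list(per_type = per_type, overall = overall, warning = warn)
}
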