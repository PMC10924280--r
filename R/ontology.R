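## Common cell-type nomenclature across engines plus fine-grained-to-major
## aggregation. Fractions aggregate by SUM (preserves the simplex); scores
## aggregate by MEAN (scores are not additive, and summing would inflate
## types with many sub-phenotypes). Both modes are overridable.

#' Construct a CellTypeOntology
#'
#' @param harmonization data.frame with character columns `method`, `raw`,
#'   `canonical` mapping a method's raw output label to the canonical
#'   vocabulary.
#' @param hierarchy named character vector: `names()` are fine-grained
#'   labels, values are major labels (each fine label maps to exactly one
#'   major).
#' @param majorRoster ordered character vector of major labels; defaults to
#'   the unique values of `hierarchy`.
#' @return A validated [CellTypeOntology-class].
#' @export
CellTypeOntology <- function(harmonization = NULL, hierarchy = character(),
                             majorRoster = NULL) {
  if (is.null(harmonization))
    harmonization <- data.frame(method = character(), raw = character(),
                                canonical = character())
  harmonization <- harmonization[, c("method", "raw", "canonical")]
  if (is.null(majorRoster)) majorRoster <- unique(unname(hierarchy))
  new("CellTypeOntology", harmonization = harmonization,
      hierarchy = hierarchy, majorRoster = majorRoster)
}

#' The bundled default ontology
#'
#' Harmonization entries for the bundled engines, a fine-grained phenotype
#' hierarchy (> 180 fine labels), and a roster of 19 major immune and
#' stromal cell types. The major roster cardinality (19) is a structural
#' property of the bundled hierarchy; the concrete label names are a
#' curated vocabulary editable via the shipped TSVs.
#'
#' @return A [CellTypeOntology-class].
#' @export
defaultOntology <- function() {
  harm <- read.delim(system.file("extdata", "harmonization.tsv",
                                 package = "murideconv", mustWork = TRUE),
                     stringsAsFactors = FALSE)
  hier <- read.delim(system.file("extdata", "celltype_hierarchy.tsv",
                                 package = "murideconv", mustWork = TRUE),
                     stringsAsFactors = FALSE)
  CellTypeOntology(harmonization = harm,
                   hierarchy = setNames(hier$major, hier$fine),
                   majorRoster = unique(hier$major))
}

#' Harmonize a result's cell-type labels to the canonical vocabulary
#'
#' Raw labels with a `(method, raw)` entry in the ontology are replaced by
#' their canonical label; labels without an entry pass through unchanged
#' (with a notice). Two raw labels of one method mapping to the same
#' canonical label is an error.
#'
#' @param result a [DeconvolutionResult-class].
#' @param ontology a [CellTypeOntology-class]; default [defaultOntology()].
#' @return The relabeled [DeconvolutionResult-class].
#' @export
harmonizeResult <- function(result, ontology = defaultOntology()) {
  stopifnot(is(result, "DeconvolutionResult"), is(ontology, "CellTypeOntology"))
  h <- ontology@harmonization
  h <- h[h$method == result@methodName, , drop = FALSE]
  raw <- rownames(result@values)
  canon <- raw
  hit <- match(raw, h$raw)
  canon[!is.na(hit)] <- h$canonical[hit[!is.na(hit)]]
  if (anyDuplicated(canon))
    stop(sprintf("harmonization collision for method '%s': labels %s map to one canonical label",
                 result@methodName,
                 paste(raw[duplicated(canon) | duplicated(canon, fromLast = TRUE)],
                       collapse = ", ")))
  n_pass <- sum(is.na(hit))
  if (n_pass > 0L && n_pass < length(raw))
    message(sprintf("%d label(s) had no harmonization entry; passed through",
                    n_pass))
  out <- result@values
  rownames(out) <- canon
  DeconvolutionResult(out, estimateType = result@estimateType,
                      methodName = result@methodName,
                      hasUnknownRow = result@hasUnknownRow,
                      metadata = result@metadata)
}

#' Aggregate fine-grained estimates to major cell types
#'
#' Each result label is looked up in the ontology hierarchy and estimates
#' are aggregated per major label: fractions by `sum` (column sums, and
#' hence the simplex, are conserved exactly), scores by `mean`. Labels not
#' in the hierarchy are collected under `"unassigned"` with a warning; an
#' `"uncharacterized"` (unknown content) row passes through unchanged.
#'
#' @inheritParams harmonizeResult
#' @param aggregate override the aggregation: `"sum"` or `"mean"`; default
#'   `NULL` picks by estimate type.
#' @return A [DeconvolutionResult-class] at major-type resolution.
#' @export
groupToMajor <- function(result, ontology = defaultOntology(),
                         aggregate = NULL) {
  stopifnot(is(result, "DeconvolutionResult"), is(ontology, "CellTypeOntology"))
  if (is.null(aggregate))
    aggregate <- if (result@estimateType == "fraction") "sum" else "mean"
  aggregate <- match.arg(aggregate, c("sum", "mean"))
  labs <- rownames(result@values)
  major <- unname(ontology@hierarchy[labs])
  keep_as_is <- labs == "uncharacterized"
  major[keep_as_is] <- "uncharacterized"
  unmapped <- is.na(major)
  if (any(unmapped)) {
    warning(sprintf("%d label(s) not in hierarchy grouped as 'unassigned': %s",
                    sum(unmapped), paste(labs[unmapped], collapse = ", ")))
    major[unmapped] <- "unassigned"
  }
  groups <- unique(major)
  ordered_groups <- c(intersect(ontology@majorRoster, groups),
                      setdiff(groups, ontology@majorRoster))
  out <- do.call(rbind, lapply(ordered_groups, function(g) {
    block <- result@values[major == g, , drop = FALSE]
    if (aggregate == "sum") colSums(block) else colMeans(block)
  }))
  rownames(out) <- ordered_groups
  DeconvolutionResult(out, estimateType = result@estimateType,
                      methodName = result@methodName,
                      hasUnknownRow = result@hasUnknownRow &&
                        "uncharacterized" %in% ordered_groups,
                      metadata = c(result@metadata,
                                   list(grouped_by = aggregate)))
}
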