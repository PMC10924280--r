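## Mouse-to-human orthologous gene mapping: lets human-trained signatures and
## engines run on murine expression matrices. Mapping operates in linear
## space only (summing log-scale values across orthologs is meaningless).

#' Load a two-column ortholog mapping table
#'
#' Expects a TSV with header `source<TAB>target` and one symbol pair per
#' line. Exact duplicate pairs are removed (count reported).
#'
#' @param path TSV file path.
#' @return A [GeneMappingTable-class].
#' @export
loadMappingTable <- function(path) {
  if (!file.exists(path)) .formatError("file not found: %s", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("source", "target") %in% colnames(df)))
    .formatError("%s: mapping table needs 'source' and 'target' columns", path)
  df <- df[, c("source", "target")]
  if (any(is.na(df$source) | is.na(df$target) |
          !nzchar(trimws(df$source)) | !nzchar(trimws(df$target))))
    .formatError("%s: empty symbol in mapping table", path)
  n0 <- nrow(df)
  df <- unique(df)
  if (nrow(df) < n0)
    message(sprintf("removed %d exact duplicate mapping pair(s)", n0 - nrow(df)))
  tryCatch(GeneMappingTable(df$source, df$target,
                            provenance = sprintf("file:%s", basename(path))),
           error = function(e) .validationError("%s: %s", path,
                                                conditionMessage(e)))
}

#' Bundled mouse-to-human ortholog table
#'
#' A compact curated table of one-to-one immune/stromal-relevant mouse-human
#' symbol pairs shipped with the package, adequate for examples and tests;
#' genome-wide tables should be supplied by the user via
#' [loadMappingTable()].
#'
#' @return A [GeneMappingTable-class].
#' @export
bundledOrthologTable <- function() {
  loadMappingTable(system.file("extdata", "ortholog_mouse_human.tsv",
                               package = "murideconv", mustWork = TRUE))
}

#' Mouse-to-human symbol-case fallback mapping
#'
#' Murine symbols conventionally differ from their human orthologs only by
#' case (`Cd8a` vs `CD8A`); this heuristic maps every input symbol to its
#' uppercase form. It is a fallback for genes absent from a curated table
#' and is flagged as such in the table provenance. Applying it to symbols
#' that are already uppercase yields the identity mapping.
#'
#' @param geneIds character vector of gene symbols.
#' @return A [GeneMappingTable-class] with provenance
#'   `"case-convention heuristic"`.
#' @examples
#' mappingPairs(caseConventionFallback(c("Cd8a", "Gzmb")))
#' @export
caseConventionFallback <- function(geneIds) {
  geneIds <- unique(as.character(geneIds))
  new("GeneMappingTable",
      pairs = data.frame(source = geneIds, target = toupper(geneIds),
                         stringsAsFactors = FALSE),
      provenance = "case-convention heuristic")
}

#' Convert a murine expression matrix into human gene space
#'
#' Rows are relabeled from source to target symbols via the mapping table.
#' Source genes without a table entry are dropped (and counted). Several
#' source genes hitting one target are combined per `manyToOne`
#' (default `"sum"`, conserving signal). One source gene hitting several
#' targets is resolved per `oneToMany`: `"first"` keeps the
#' alphabetically smallest target (avoids double counting), `"duplicate"`
#' copies the row to every target, `"drop"` removes the ambiguous gene.
#'
#' Under policy `(sum, drop)` the total signal of mapped, unambiguous genes
#' is conserved exactly; under a bijective table the operation is a pure
#' row relabeling.
#'
#' @param expr an [ExpressionMatrix-class] with unit `"TPM"` or `"counts"`
#'   (linear scale required).
#' @param table a [GeneMappingTable-class].
#' @param manyToOne `"sum"`, `"mean"` or `"max"`.
#' @param oneToMany `"first"`, `"duplicate"` or `"drop"`.
#' @param warnBelow warn when the mapped fraction of source genes falls
#'   below this value (default 0.6).
#' @return A list with elements `expr` (converted [ExpressionMatrix-class])
#'   and `report` (a `MappingReport` list: `n_source_genes`, `n_mapped`,
#'   `n_dropped`, `n_one_to_many`, `n_many_to_one`, `dropped_symbols`,
#'   `policies`).
#' @examples
#' m <- matrix(c(2, 4), ncol = 1, dimnames = list(c("A", "B"), "s1"))
#' tb <- GeneMappingTable(c("A", "B"), c("X", "X"))
#' convertExpression(ExpressionMatrix(m, "TPM"), tb)$expr
#' @export
convertExpression <- function(expr, table,
                              manyToOne = c("sum", "mean", "max"),
                              oneToMany = c("first", "duplicate", "drop"),
                              warnBelow = 0.6) {
  stopifnot(is(expr, "ExpressionMatrix"), is(table, "GeneMappingTable"))
  manyToOne <- match.arg(manyToOne)
  oneToMany <- match.arg(oneToMany)
  if (!expr@unit %in% c("TPM", "counts"))
    .validationError(
      "ortholog conversion requires linear-scale input (TPM/counts), got '%s'",
      expr@unit)

  src_genes <- rownames(expr@values)
  pairs <- table@pairs[table@pairs$source %in% src_genes, , drop = FALSE]

  # resolve one-to-many at the source-symbol level
  n_one_to_many <- 0L
  if (nrow(pairs)) {
    tab <- table(pairs$source)
    ambi <- names(tab)[tab > 1L]
    n_one_to_many <- length(ambi)
    if (n_one_to_many && oneToMany != "duplicate") {
      if (oneToMany == "first") {
        pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
        pairs <- pairs[!duplicated(pairs$source), , drop = FALSE]
      } else {                                   # drop
        pairs <- pairs[!pairs$source %in% ambi, , drop = FALSE]
      }
    }
  }

  mapped_src <- unique(pairs$source)
  dropped <- setdiff(src_genes, mapped_src)
  if (!length(mapped_src))
    .validationError(
      "no gene mapped: wrong species or wrong mapping table?")
  frac <- length(mapped_src) / length(src_genes)
  if (frac < warnBelow)
    warning(sprintf("only %.1f%% of source genes mapped (threshold %.0f%%)",
                    100 * frac, 100 * warnBelow))

  # expand rows (duplicate policy may repeat a source row), then aggregate
  out <- expr@values[pairs$source, , drop = FALSE]
  rownames(out) <- pairs$target
  tgt_tab <- table(pairs$target)
  n_many_to_one <- sum(tgt_tab > 1L)
  out <- .collapseDuplicateRows(out, manyToOne)
  out <- out[order(rownames(out)), , drop = FALSE]

  report <- list(
    n_source_genes = length(src_genes),
    n_mapped = length(mapped_src),
    n_dropped = length(dropped),
    n_one_to_many = n_one_to_many,
    n_many_to_one = as.integer(n_many_to_one),
    dropped_symbols = dropped,
    policies = c(many_to_one = manyToOne, one_to_many = oneToMany),
    provenance = table@provenance)
  stopifnot(report$n_mapped + report$n_dropped == report$n_source_genes)

  list(expr = ExpressionMatrix(out, unit = expr@unit), report = report)
}
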