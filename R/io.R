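## On-disk formats: genes-in-rows TSV/CSV matrices, GMT gene sets, result
## tables with a provenance comment line. Orientation is fixed; no
## auto-transposition is ever attempted.

.formatError <- function(...) {
  stop(structure(class = c("murideconv_format_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1L))))
}

.validationError <- function(...) {
  stop(structure(class = c("murideconv_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1L))))
}

.readMatrixFile <- function(path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) .formatError("file not found: %s", path)
  sep <- if (fmt == "tsv") "\t" else ","
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) .formatError("cannot parse %s: %s", path,
                                     conditionMessage(e)))
  if (ncol(df) < 2L)
    .formatError("%s: need a gene-id column plus at least one data column", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    .formatError("%s: non-numeric values in data columns", path)
  if (anyDuplicated(colnames(m)))
    .formatError("%s: duplicate column ids in header", path)
  rownames(m) <- ids
  m
}

.collapseDuplicateRows <- function(m, policy = c("sum", "mean", "max")) {
  policy <- match.arg(policy)
  if (!anyDuplicated(rownames(m))) return(m)
  ids <- rownames(m)
  n_dup <- sum(duplicated(ids))
  agg <- switch(policy,
    sum  = rowsum(m, group = ids, reorder = FALSE),
    mean = rowsum(m, group = ids, reorder = FALSE) / as.vector(table(ids)[unique(ids)]),
    max  = {
      u <- unique(ids)
      out <- do.call(rbind, lapply(u, function(g)
        apply(m[ids == g, , drop = FALSE], 2L, max)))
      rownames(out) <- u
      out
    })
  message(sprintf("collapsed %d duplicate gene row(s) by '%s'", n_dup, policy))
  agg[unique(ids), , drop = FALSE]
}

#' Read a bulk expression matrix from TSV/CSV
#'
#' Genes in rows (first column = gene symbols), samples in columns (header
#' row = sample ids). Duplicate gene rows are collapsed per `duplicateGenes`
#' (default `"sum"`, which conserves total signal for count-like data); a
#' collapse is reported via [message()].
#'
#' @param path input file.
#' @param fmt `"tsv"` or `"csv"`.
#' @param unit declared unit of the values: `"TPM"`, `"counts"` or
#'   `"log2_TPM"`. Log-scale data must be declared; it is never detected.
#' @param duplicateGenes collapse policy for duplicated gene symbols:
#'   `"sum"`, `"mean"` or `"max"`.
#' @return An [ExpressionMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "Cd8a\t1\t2", "Cd4\t3\t4"), f)
#' readExpression(f, unit = "TPM")
#' @export
readExpression <- function(path, fmt = c("tsv", "csv"),
                           unit = c("TPM", "counts", "log2_TPM"),
                           duplicateGenes = c("sum", "mean", "max")) {
  unit <- match.arg(unit)
  m <- .readMatrixFile(path, fmt)
  m <- .collapseDuplicateRows(m, duplicateGenes)
  if (unit %in% c("TPM", "counts") && any(m < 0, na.rm = TRUE))
    .validationError("%s: negative values are invalid for unit '%s'", path, unit)
  tryCatch(ExpressionMatrix(m, unit = unit),
           error = function(e) .validationError("%s: %s", path,
                                                conditionMessage(e)))
}

#' Read a signature matrix from TSV/CSV
#'
#' Genes in rows, cell types in columns. An all-zero cell-type column is a
#' validation error.
#'
#' @inheritParams readExpression
#' @param mrnaScaling optional named positive numeric per cell type.
#' @return A [SignatureMatrix-class].
#' @export
readSignature <- function(path, fmt = c("tsv", "csv"), mrnaScaling = NULL) {
  m <- .readMatrixFile(path, fmt)
  m <- .collapseDuplicateRows(m, "sum")
  tryCatch(SignatureMatrix(m, mrnaScaling = mrnaScaling),
           error = function(e) .validationError("%s: %s", path,
                                                conditionMessage(e)))
}

#' Read (optionally signed) gene sets from a GMT file
#'
#' Standard GMT: one set per line as `name<TAB>description<TAB>gene...`.
#' Signed dialect: a gene token with a trailing `"-"` is a down marker
#' (weight -1); all other tokens are up markers (weight +1).
#'
#' @param path GMT file.
#' @return A [WeightedGeneSetCollection-class], one entry per set.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) .formatError("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .formatError("%s: empty GMT file", path)
  sets <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L)
      .formatError("%s line %d: fewer than 3 tab-separated fields", path, i)
    nm <- tok[[1L]]
    if (nm %in% names(sets))
      .validationError("%s: duplicate gene-set name '%s'", path, nm)
    genes <- tok[-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    down <- grepl("-$", genes)
    w <- ifelse(down, -1, 1)
    names(w) <- sub("-$", "", genes)
    sets[[nm]] <- w
  }
  tryCatch(WeightedGeneSetCollection(sets),
           error = function(e) .validationError("%s: %s", path,
                                                conditionMessage(e)))
}

#' Write / read a deconvolution result as TSV
#'
#' Cell types in rows, samples in columns, preceded by a comment line
#' `# method=<name> estimate_type=<fraction|score>` so a result file is
#' self-describing. Writing revalidates the object, so a fraction result
#' violating the simplex invariant is refused.
#'
#' @param result a [DeconvolutionResult-class].
#' @param path output (input) TSV path.
#' @return `writeResult` returns `path` invisibly; `readResult` returns the
#'   reconstructed [DeconvolutionResult-class].
#' @export
writeResult <- function(result, path) {
  stopifnot(is(result, "DeconvolutionResult"))
  validObject(result)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# method=%s estimate_type=%s",
                     result@methodName, result@estimateType), con)
  df <- data.frame(cell_type = rownames(result@values),
                   result@values, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResult
#' @export
readResult <- function(path) {
  if (!file.exists(path)) .formatError("file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  meth <- "unknown"; etype <- "score"
  if (startsWith(hdr, "#")) {
    meth <- sub(".*method=(\\S+).*", "\\1", hdr)
    etype <- sub(".*estimate_type=(\\S+).*", "\\1", hdr)
  }
  m <- .readMatrixFile(path, "tsv")
  DeconvolutionResult(m, estimateType = etype, methodName = meth,
                      hasUnknownRow = "uncharacterized" %in% rownames(m))
}

#' Write an expression or signature matrix as TSV
#'
#' @param x an [ExpressionMatrix-class] or [SignatureMatrix-class].
#' @param path output TSV path.
#' @param idColumn name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path, idColumn = "gene") {
  m <- as.matrix(x)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalize counts to a per-million scale
#'
#' Counts-per-million turns a counts matrix into a TPM-like per-million
#' scale (gene length is not corrected, as lengths are unavailable from
#' count matrices); the result is tagged `"TPM"` so per-million engines
#' accept it.
#'
#' @param expr an [ExpressionMatrix-class] with unit `"counts"`.
#' @return An [ExpressionMatrix-class] with unit `"TPM"`, columns summing
#'   to 1e6.
#' @export
cpmNormalize <- function(expr) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (expr@unit != "counts")
    .validationError("cpmNormalize expects unit 'counts', got '%s'", expr@unit)
  cs <- colSums(expr@values)
  if (any(cs <= 0)) .validationError("cannot CPM-normalize an all-zero sample")
  ExpressionMatrix(sweep(expr@values, 2L, cs, "/") * 1e6, unit = "TPM")
}
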