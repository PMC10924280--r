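## Benchmarking of deconvolution estimates against known composition:
## per-cell-type Pearson correlation across samples, plus RMSE for
## fraction-type estimates (scores live on arbitrary scales, so an RMSE
## against fractions would be meaningless for them).

#' Evaluate a deconvolution result against ground-truth fractions
#'
#' Cell-type labels are aligned directly, optionally after harmonization
#' and fine-to-major grouping via an ontology. For each aligned cell type
#' the Pearson correlation between estimate and truth is computed across
#' samples (per-sample mode across cell types is available behind
#' `perSample`); RMSE is reported only for fraction-type results. Types
#' with zero truth variance, or fewer than `minSamples` paired samples,
#' get `NA` correlation with a flag (a correlation over 2 points is always
#' +/-1). Missing estimate values are dropped pairwise.
#'
#' @param result a [DeconvolutionResult-class].
#' @param truth numeric matrix, cell types x samples, of true fractions.
#' @param ontology optional [CellTypeOntology-class]; when given, the
#'   result is harmonized first, and if `groupMajor = TRUE` both result
#'   and truth are aggregated to major types before alignment.
#' @param groupMajor aggregate both sides to major types (truth rows by
#'   sum) before comparing.
#' @param minSamples minimum paired samples for reporting a correlation
#'   (default 3).
#' @param perSample if `TRUE`, correlate across cell types within each
#'   sample instead (one row per sample).
#' @return A data.frame (`BenchmarkReport`): `method`, `cell_type`,
#'   `n_samples`, `pearson_r`, `rmse`, `flag` — with attribute
#'   `"truth_flavor_note"` carrying the alignment log.
#' @export
evaluateDeconvolution <- function(result, truth, ontology = NULL,
                                  groupMajor = FALSE, minSamples = 3L,
                                  perSample = FALSE) {
  stopifnot(is(result, "DeconvolutionResult"), is.matrix(truth))
  log <- character()
  if (!is.null(ontology)) {
    result <- harmonizeResult(result, ontology)
    log <- c(log, "harmonized result labels")
    if (groupMajor) {
      result <- groupToMajor(result, ontology)
      hier <- ontology@hierarchy
      tmaj <- unname(hier[rownames(truth)])
      tmaj[is.na(tmaj)] <- rownames(truth)[is.na(tmaj)]
      truth <- rowsum(truth, tmaj)
      log <- c(log, "grouped result and truth to major types")
    }
  }
  est <- result@values
  shared_s <- intersect(colnames(est), colnames(truth))
  if (!length(shared_s)) stop("no shared sample ids between result and truth")
  shared_t <- intersect(rownames(est), rownames(truth))
  if (!length(shared_t))
    stop(sprintf("no shared cell types.\n  result: %s\n  truth:  %s",
                 paste(rownames(est), collapse = ", "),
                 paste(rownames(truth), collapse = ", ")))
  est <- est[shared_t, shared_s, drop = FALSE]
  tru <- truth[shared_t, shared_s, drop = FALSE]
  is_frac <- result@estimateType == "fraction"

  if (perSample) { est <- t(est); tru <- t(tru) }
  units <- rownames(est)
  rows <- lapply(units, function(u) {
    e <- est[u, ]; g <- tru[u, ]
    ok <- is.finite(e) & is.finite(g)
    n <- sum(ok)
    flag <- ""
    r <- NA_real_
    if (n < minSamples) flag <- "too_few_samples"
    else if (sd(g[ok]) == 0) flag <- "zero_truth_variance"
    else if (sd(e[ok]) == 0) flag <- "zero_estimate_variance"
    else r <- cor(e[ok], g[ok])
    rmse <- if (is_frac && !perSample && n > 0)
      sqrt(mean((e[ok] - g[ok])^2)) else NA_real_
    data.frame(method = result@methodName,
               cell_type = u, n_samples = n, pearson_r = r, rmse = rmse,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (perSample) names(out)[names(out) == "cell_type"] <- "sample_id"
  attr(out, "truth_flavor_note") <- paste(log, collapse = "; ")
  out
}

#' Combine benchmark reports into one long table
#'
#' @param reports list of data.frames from [evaluateDeconvolution()].
#' @return A long data.frame with one row per (method, cell type); method
#'   and cell-type combinations missing from a report appear with `NA`
#'   metrics.
#' @export
crossMethodTable <- function(reports) {
  cols <- c("method", "cell_type", "n_samples", "pearson_r", "rmse", "flag")
  if (!length(reports))
    return(data.frame(method = character(), cell_type = character(),
                      n_samples = integer(), pearson_r = numeric(),
                      rmse = numeric(), flag = character()))
  long <- do.call(rbind, lapply(reports, function(r) r[, cols]))
  grid <- expand.grid(method = unique(long$method),
                      cell_type = unique(long$cell_type),
                      stringsAsFactors = FALSE)
  out <- merge(grid, long, by = c("method", "cell_type"), all.x = TRUE,
               sort = TRUE)
  out[order(out$method, out$cell_type), , drop = FALSE]
}
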