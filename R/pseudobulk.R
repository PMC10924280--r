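## Synthetic single-cell reference generator and pseudo-bulk construction.
## Pseudo-bulk samples are built the way simulation frameworks for
## deconvolution benchmarking build them: sample cells of each type (with
## replacement) at chosen proportions and sum their count profiles.

#' Parameters for the synthetic single-cell reference
#'
#' Counts for gene g in a cell of type t are negative binomial with mean
#' `L_c * mu_tg` and dispersion `nbDispersion`
#' (variance = mean + mean^2 / dispersion), where `mu_tg` is
#' `baseMean * markerFold` if g is one of the type's planted marker genes
#' and `baseMean` otherwise, and the per-cell library factor `L_c` is
#' log-normal with log-sd `libsizeSigma`. Planted marker blocks are
#' disjoint across types. `nbDispersion = Inf` selects the Poisson limit.
#'
#' @param nCellTypes number of cell types.
#' @param nGenes total genes; must be >= `nCellTypes * nMarkersPerType`.
#' @param nMarkersPerType planted markers per type.
#' @param markerFold marker over background mean fold (> 1).
#' @param baseMean background mean count per gene (> 0).
#' @param nbDispersion negative-binomial dispersion (> 0, or `Inf` for
#'   Poisson).
#' @param libsizeSigma log-normal sd of per-cell library factors (>= 0).
#' @param nCellsPerType cells simulated per type.
#' @param seed integer seed.
#' @return A validated parameter list of class `"SCSimParams"`.
#' @export
scSimParams <- function(nCellTypes = 5L, nGenes = 2000L,
                        nMarkersPerType = 40L, markerFold = 6,
                        baseMean = 2, nbDispersion = 2,
                        libsizeSigma = 0.3, nCellsPerType = 100L,
                        seed = 1L) {
  p <- list(nCellTypes = as.integer(nCellTypes), nGenes = as.integer(nGenes),
            nMarkersPerType = as.integer(nMarkersPerType),
            markerFold = markerFold, baseMean = baseMean,
            nbDispersion = nbDispersion, libsizeSigma = libsizeSigma,
            nCellsPerType = as.integer(nCellsPerType),
            seed = as.integer(seed))
  if (p$nCellTypes < 1L || p$nGenes < 1L || p$nMarkersPerType < 0L)
    .validationError("counts in SCSimParams must be positive")
  if (p$nMarkersPerType * p$nCellTypes > p$nGenes)
    .validationError("marker blocks (%d x %d) exceed the gene count (%d)",
                     p$nMarkersPerType, p$nCellTypes, p$nGenes)
  if (p$markerFold < 1 || p$baseMean <= 0 || p$nbDispersion <= 0 ||
      p$libsizeSigma < 0)
    .validationError("markerFold >= 1, baseMean > 0, nbDispersion > 0 and libsizeSigma >= 0 required")
  structure(p, class = "SCSimParams")
}

#' Simulate a labeled single-cell count reference
#'
#' @param params an [scSimParams()] object.
#' @return A list: `expr` (cells-as-samples counts
#'   [ExpressionMatrix-class]), `labels` (named character, cell ->
#'   cell type), `plantedMarkers` (list of marker gene ids per type),
#'   `params`.
#' @examples
#' ref <- simulateSCReference(scSimParams(nCellTypes = 2, nGenes = 100,
#'   nMarkersPerType = 5, nCellsPerType = 20, seed = 7))
#' table(ref$labels)
#' @export
simulateSCReference <- function(params) {
  stopifnot(inherits(params, "SCSimParams"))
  p <- params
  genes <- sprintf("gene%05d", seq_len(p$nGenes))
  types <- sprintf("type%s", LETTERS[seq_len(p$nCellTypes)])
  planted <- lapply(seq_len(p$nCellTypes), function(i)
    genes[((i - 1L) * p$nMarkersPerType + 1L):(i * p$nMarkersPerType)])
  names(planted) <- types

  mu <- matrix(p$baseMean, p$nGenes, p$nCellTypes,
               dimnames = list(genes, types))
  for (t in types) mu[planted[[t]], t] <- p$baseMean * p$markerFold

  n_cells <- p$nCellTypes * p$nCellsPerType
  labels <- rep(types, each = p$nCellsPerType)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  names(labels) <- cell_ids

  counts <- .withSeed(p$seed, {
    L <- rlnorm(n_cells, 0, p$libsizeSigma)
    m <- matrix(0L, p$nGenes, n_cells, dimnames = list(genes, cell_ids))
    for (c in seq_len(n_cells)) {
      mu_c <- L[c] * mu[, labels[c]]
      m[, c] <- if (is.infinite(p$nbDispersion)) rpois(p$nGenes, mu_c)
                else rnbinom(p$nGenes, mu = mu_c, size = p$nbDispersion)
    }
    m
  })
  list(expr = ExpressionMatrix(counts, unit = "counts"), labels = labels,
       plantedMarkers = planted, params = p)
}

# Dirichlet draw via gamma normalization
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = k)
  sweep(x, 2L, colSums(x), "/")
}

#' Build pseudo-bulk samples from a labeled single-cell reference
#'
#' Per sample: draw per-type cell counts from a multinomial over the
#' requested proportions, sample that many cells of each type with
#' replacement, and sum their count profiles (each cell's profile
#' multiplied by its type's `mrnaBias` factor). Ground truth is returned
#' in two flavors: realized cell-count fractions, and mRNA-weighted
#' fractions (realized counts weighted by `mrnaBias x` the type's mean
#' library size in the reference, re-normalized) - the latter is what
#' regression engines on un-normalized signatures recover.
#'
#' @param sc single-cell counts [ExpressionMatrix-class] (cells as
#'   columns).
#' @param labels named character vector, cell id -> cell type.
#' @param fractions requested proportions: a numeric vector (one set of
#'   proportions reused for every sample) or a types x samples matrix;
#'   `NULL` to draw each sample's proportions from a Dirichlet.
#' @param nSamples number of pseudo-bulk samples (default 20).
#' @param nCellsPerSample cells summed per sample (default 500).
#' @param mrnaBias optional named positive per-type scalars (default all
#'   1).
#' @param dirichletAlpha concentration for Dirichlet-drawn proportions
#'   (scalar or per-type vector; default 1, used when `fractions` is
#'   `NULL`).
#' @param seed integer seed.
#' @return A [PseudoBulkDataset-class].
#' @export
simulatePseudobulk <- function(sc, labels, fractions = NULL, nSamples = 20L,
                               nCellsPerSample = 500L, mrnaBias = NULL,
                               dirichletAlpha = 1, seed = 1L) {
  stopifnot(is(sc, "ExpressionMatrix"))
  cells <- colnames(sc@values)
  if (!all(cells %in% names(labels)))
    .validationError("labels must cover every cell in the reference")
  labels <- labels[cells]
  types <- sort(unique(labels))

  if (is.null(mrnaBias)) mrnaBias <- setNames(rep(1, length(types)), types)
  if (!all(types %in% names(mrnaBias)) || any(mrnaBias <= 0))
    .validationError("mrnaBias needs one positive value per cell type")

  if (!is.null(fractions)) {
    P <- if (is.matrix(fractions)) fractions
         else matrix(fractions, ncol = nSamples, nrow = length(fractions),
                     dimnames = list(names(fractions), NULL))
    if (is.null(rownames(P)))
      .validationError("fractions must name the cell types")
    missing_t <- setdiff(rownames(P), types)
    if (length(missing_t))
      .validationError("requested cell type(s) absent from the reference: %s",
                       paste(missing_t, collapse = ", "))
    nSamples <- ncol(P)
  }

  lib <- colSums(sc@values)
  mean_lib <- vapply(types, function(t) mean(lib[labels == t]), numeric(1))
  sample_ids <- sprintf("sample%02d", seq_len(nSamples))

  res <- .withSeed(seed, {
    if (is.null(fractions)) {
      alpha <- if (length(dirichletAlpha) == 1L)
        rep(dirichletAlpha, length(types)) else dirichletAlpha[types]
      P <- .rdirichlet(nSamples, alpha)
      rownames(P) <- types
    }
    use_types <- rownames(P)
    bulk <- matrix(0, nrow(sc@values), nSamples,
                   dimnames = list(rownames(sc@values), sample_ids))
    realized <- matrix(0L, length(use_types), nSamples,
                       dimnames = list(use_types, sample_ids))
    for (s in seq_len(nSamples)) {
      n_t <- as.vector(rmultinom(1L, nCellsPerSample, P[, s]))
      realized[, s] <- n_t
      for (i in seq_along(use_types)) {
        if (n_t[i] == 0L) next
        pool <- cells[labels == use_types[i]]
        pick <- sample(pool, n_t[i], replace = TRUE)
        bulk[, s] <- bulk[, s] +
          rowSums(sc@values[, pick, drop = FALSE]) * mrnaBias[use_types[i]]
      }
    }
    list(bulk = bulk, realized = realized)
  })

  frac_cells <- sweep(res$realized, 2L, colSums(res$realized), "/")
  w <- res$realized * (mrnaBias[rownames(res$realized)] *
                       mean_lib[rownames(res$realized)])
  frac_mrna <- sweep(w, 2L, colSums(w), "/")

  new("PseudoBulkDataset",
      expr = ExpressionMatrix(res$bulk, unit = "counts"),
      trueFractionsCells = frac_cells, trueFractionsMrna = frac_mrna,
      params = list(nSamples = nSamples, nCellsPerSample = nCellsPerSample,
                    mrnaBias = mrnaBias, dirichletAlpha = dirichletAlpha,
                    seed = seed))
}
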