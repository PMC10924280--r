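# murideconv

Cell-type deconvolution of **mouse** bulk RNA-seq.

Bulk RNA-seq averages expression over all cells in a tissue. murideconv
unmixes that average: given a genes × samples expression matrix, it
estimates how much of each immune, stromal or user-defined cell type each
sample contains. For human data this task is served by a mature tool
ecosystem; for mouse models — the workhorse of preclinical immunology —
tooling is sparser. murideconv implements the main algorithmic families of
the field natively for murine data, plus an orthologous-gene-mapping layer
so human-trained signatures can be applied to mouse matrices, behind one
interface, one result container, and one cell-type nomenclature.

## Engines

| Method | Family | Output |
|---|---|---|
| `medianMarkerScore` | marker-gene median (MCP-counter style) | score |
| `signedRankScore` | signed normalized-rank gene-set score (BASE style) | score |
| `clsDeconvolve` | constrained least squares with unknown content (EPIC / least-squares style) | fraction |
| `nusvrDeconvolve` | linear ν-SVR (CIBERSORT / SVR style) | fraction |
| `elasticnetDeconvolve` | repeated-subsample elastic net (DCQ style) | score |

The core model behind the fraction engines: a mixture $b \in
\mathbb{R}^G$ (TPM) is a non-negative combination of cell-type profiles,
$b \approx S f$ with signature $S \in \mathbb{R}^{G \times K}$,
$f \ge 0$, $\sum_t f_t = 1$. `clsDeconvolve` solves

$$\min_{f \ge 0,\; \sum f \le 1} \big\lVert W^{1/2}(S f - b)\big\rVert_2^2$$

and reports $1 - \sum_t f_t$ as the `"uncharacterized"` fraction — cells
present in the tissue but missing from the signature. *Scores* are
comparable for one cell type between samples; *fractions* are additionally
comparable across cell types within a sample. Every result carries this
distinction (`estimateType`) and the benchmark module enforces it (RMSE is
only computed for fractions).

Around the engines:

* `convertExpression` / `caseConventionFallback` / `bundledOrthologTable` —
  mouse→human symbol mapping with explicit many-to-one / one-to-many
  policies and a mapping report;
* `getResource` — bundled murine marker sets (14 cell types), signature
  matrix (10 cell types) and a >180-phenotype roster grouped into 19 major
  types (curated structural stand-ins, editable TSV/GMT);
* `buildSignatureFromSC` — signature + marker construction from labeled
  single-cell counts;
* `simulateSCReference` / `simulatePseudobulk` — negative-binomial
  single-cell simulation and pseudo-bulk construction with known ground
  truth in cell-count and mRNA-weighted flavors;
* `harmonizeResult` / `groupToMajor` — common nomenclature and
  fine-to-major aggregation (sum for fractions, mean for scores);
* `evaluateDeconvolution` / `crossMethodTable` — per-cell-type Pearson
  correlation and RMSE against ground truth;
* `runMethod` — one dispatch point over everything, including automatic
  ortholog conversion for human-signature methods on murine input.

## Worked example

Deconvolve two synthetic spleen-like mixtures built from the bundled
10-cell-type signature:

```r
library(murideconv)

sig <- getResource("seqimmucc_like")          # genes x 10 cell types, TPM-like
S <- as.matrix(sig)
f1 <- c(0.35, 0.25, 0.15, 0.10, 0.05, 0.04, 0.03, 0.01, 0.01, 0.01)
B <- cbind(spleen_1 = as.vector(S %*% f1),
           spleen_2 = as.vector(S %*% rev(f1)))
rownames(B) <- rownames(S)
expr <- ExpressionMatrix(B, "TPM")

res <- runMethod(expr, "cls", allowUnknown = TRUE)
round(as.matrix(res), 3)
```

```
                spleen_1 spleen_2
B cell              0.35     0.01
T cell CD4+         0.25     0.01
T cell CD8+         0.15     0.01
NK cell             0.10     0.03
Monocyte            0.05     0.04
Macrophage          0.04     0.05
Dendritic cell      0.03     0.10
Neutrophil          0.01     0.15
Eosinophil          0.01     0.25
Mast cell           0.01     0.35
uncharacterized     0.00     0.00
```

Each column is a point on the simplex: the generating fractions are
recovered exactly on these noiseless mixtures, and the
`uncharacterized` row is 0 because nothing in the mixtures lies outside
the signature. On real data that row absorbs cell types the signature
does not describe.

A command-line wrapper over the same functions ships at
`inst/cli/murideconv.R` (subcommands `deconvolute`, `map-orthologs`,
`build-signature`, `simulate`, `benchmark`, `list-methods`; every run
writes a provenance JSON next to its output).

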