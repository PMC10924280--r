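---
title: "Deconvolving murine bulk RNA-seq with murideconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving murine bulk RNA-seq with murideconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murideconv)
```

# The problem

Bulk RNA-seq measures a tissue's average expression over all of its cells.
When the question is *which cells are there and in what amounts*, that
average has to be unmixed. murideconv estimates per-cell-type abundances
from murine bulk expression matrices with the main algorithmic families
used in the immune-deconvolution field, behind one interface and one
cell-type nomenclature:

* **Median marker scoring** (`medianMarkerScore`): the abundance score of
  a cell type in a sample is the median expression of its curated marker
  genes.
* **Signed rank scoring** (`signedRankScore`): a rank-based gene-set score
  built from mean normalized ranks of up (and optionally down) markers.
* **Constrained least squares** (`clsDeconvolve`): models the mixture as a
  non-negative combination of signature profiles on the simplex, with an
  optional estimate of *uncharacterized* cellular content.
* **nu-SVR** (`nusvrDeconvolve`): support-vector regression of the
  z-scored mixture on z-scored signature columns.
* **Elastic net** (`elasticnetDeconvolve`): repeated-subsample elastic-net
  regressions whose averaged coefficients are relative abundance scores.

The first two produce **scores**: numbers comparable for one cell type
*between* samples, but not across cell types within a sample. The
regression engines against a signature produce **fractions** on the
simplex (elastic net deliberately excepted, see below). This distinction
is carried in every `DeconvolutionResult` as `estimateType` and drives
what the benchmark module will compute.

# Models and estimators

## Constrained least squares with unknown content

For a sample with mixture vector $b$ (TPM) and signature matrix $S$
(genes $\times$ cell types, TPM-like), the engine solves

$$\min_{f \ge 0} \lVert W^{1/2}(S f - b)\rVert_2^2
  \quad\text{s.t.}\quad \textstyle\sum_t f_t = 1
  \;\;(\text{or} \le 1),$$

with optional per-gene weights $W$. Under the inequality constraint the
shortfall $1 - \sum_t f_t$ is reported as the `"uncharacterized"`
fraction: cells present in the tissue but absent from the signature.

Two scale conventions make this work and are worth stating explicitly:

* The mixture is re-normalized to per-million over **all** of its genes
  *before* restriction to the genes shared with the signature. Mass
  sitting on off-signature genes then lowers the mixture's share on the
  signature genes, which is exactly the signal the unknown-content
  estimate needs. (Re-normalizing after restriction would silently erase
  it.)
* Signature columns are taken as TPM-like — per-million over the
  reference transcriptome, possibly restricted to signature genes — and
  are **not** rescaled by the solver. The bundled signature and the
  output of `buildSignatureFromSC` both satisfy this contract.

Numerically, the simplex constraint is imposed by an augmented row with
weight $10^4 \times$ the mean gene weight on top of a non-negative
least-squares solver, followed by exact re-normalization of the solution,
so fraction columns sum to 1 within 1e-9 and noiseless mixtures are
recovered to well below 1e-6. A brute-force simplex grid search (step
0.01) is kept in the test suite as an independent oracle. A duplicated
signature column makes the fit degenerate; the engine warns and still
returns a solution rather than failing.

The optional `mrnaRenormalize` step divides each known fraction by its
cell type's mRNA scaling factor and re-normalizes the known part to its
previous total (the unknown fraction is left untouched), converting
mRNA proportions into cell proportions when per-type total mRNA content
differs.

## nu-SVR

Per sample, the mixture and each signature column are z-scored over the
shared genes and a linear nu-SVR (cost fixed at $C = 1$, as is
conventional for this engine family) is fitted for each nu in
`nuGrid = c(0.25, 0.5, 0.75)`. The nu whose fit has the smallest RMSE
against the observed mixture wins; negative coefficients are clipped and
the rest normalized to sum to 1. If every coefficient clips to zero the
engine falls back to uniform fractions with a warning rather than
returning an all-zero column.

## Elastic net

Per sample, `nRepeats = 10` elastic-net regressions (mixing parameter
`l1Ratio = 0.05`, mostly ridge; regularization path picked by internal
cross-validation) are fitted on random subsets of
`subsetFraction = 0.5` of the shared genes, and coefficients are
averaged. Coefficients may be negative and are deliberately **not**
clipped or re-normalized: this engine family reports relative abundance
changes, so results are declared scores. The repeat count and mixing
parameter are package defaults, chosen once and documented here, since
the family's original settings are not published in a citable form. All
subset and fold randomness derives from an explicit `seed` argument
(default 0), making runs bit-reproducible.

## Marker scoring

`medianMarkerScore` works on `log2(TPM + 1)` by default (a pseudocount
of 1, matching common practice; raw TPM is available via
`logTransform = FALSE` for sensitivity analyses — whether the original
marker-median tools operate on log or linear scale is not settled, so
both modes are exposed). Markers absent from the matrix are ignored with
a notice; a cell type with no marker present yields an `NA` row.

`signedRankScore` ranks all $G$ genes of a sample ascending with
mid-ranks for ties, normalizes ranks to $(0, 1]$, and scores a set as
the mean normalized rank of its up genes minus that of its down genes
(minus 0.5 when there are no down genes). The 0.5 centering makes a
random set score 0 in expectation up to a bias of $1/(2G)$ — the exact
null mean of a random mean-rank is $(G+1)/(2G)$ — which is negligible at
realistic gene counts and keeps the extreme-rank behavior intuitive (a
singleton set holding the top gene scores exactly 0.5). Being rank
based, the score is invariant under any strictly monotone per-sample
transform, so no unit is enforced.

# Orthologous gene mapping

Human-trained signatures apply to murine data after translating gene
symbols. `convertExpression` relabels a murine matrix through a
two-column mapping table with explicit, logged policies:

* unmapped source genes are dropped and counted;
* many sources to one target: combined by `sum` (default; conserves
  signal for count-like data), `mean`, or `max`;
* one source to many targets: `first` (alphabetically smallest target,
  default — avoids double counting), `duplicate`, or `drop`.

Under `(sum, drop)` the total signal of mapped, unambiguous genes is
conserved exactly; a bijective table is a pure relabeling. Conversion is
linear-space only — summing log-scale values across orthologs would be
meaningless, so a `log2_TPM` input is refused. Fewer than 60% of genes
mapping triggers a warning (a common symptom of a wrong-species table).
A compact curated table (~520 immune/stromal-relevant pairs) ships with
the package for tests and examples; `caseConventionFallback` provides
the standard murine-to-human case heuristic (`Cd8a` → `CD8A`) for genes
missing from a curated table, flagged as heuristic in the provenance.

# Bundled resources and the cell-type ontology

Three murine resources ship as plain text: a 14-cell-type marker
collection (`"mmcp_like"`), a 10-cell-type TPM-like signature matrix
(`"seqimmucc_like"`), and a fine-grained roster of >180 immune phenotype
labels each mapped to one of 19 major cell types
(`"finegrained_like"`). The *cardinalities* are the structural contract;
the concrete label names and marker genes are curated stand-ins
assembled from standard immunology markers, not copies of any published
tool's resources, and are editable TSV/GMT files.

`harmonizeResult` maps each engine's raw labels onto one controlled
vocabulary (labels without an entry pass through with a notice; two raw
labels of one method colliding onto one canonical label is an error).
`groupToMajor` aggregates fine-grained estimates to the 19 major types:
fractions by **sum** (conserves column sums, hence the simplex, exactly)
and scores by **mean** (scores are not additive, and summing would
inflate types with many sub-phenotypes). Both choices are overridable
via `aggregate=`. Labels missing from the hierarchy group into
`"unassigned"` with a warning; an `"uncharacterized"` row passes through
untouched.

# The simulator and what it does (not) emulate

`simulateSCReference` draws a labeled single-cell count matrix: counts
are negative binomial with variance $\mu + \mu^2/\phi$, each type owns a
disjoint block of planted marker genes elevated `markerFold`-fold over
`baseMean`, and per-cell library factors are log-normal
(`nbDispersion = Inf` selects the Poisson limit). `simulatePseudobulk`
then draws per-type cell counts from a multinomial over requested (or
Dirichlet-sampled) proportions, samples cells **with replacement**, and
sums their profiles, optionally scaled by a per-type mRNA bias. Ground
truth is returned in two flavors — realized cell-count fractions and
mRNA-weighted fractions (realized counts $\times$ bias $\times$ the
type's mean library size, renormalized) — because regression engines on
un-normalized signatures recover the mRNA-weighted truth; the benchmark
takes either (default `"mrna"`).

The default parameters (5 cell types, 2000 genes, 40 markers per type,
fold 6, dispersion 2, library-size sigma 0.3, 100 cells per type; 20
pseudo-bulk samples of 500 cells with Dirichlet(1) proportions) are the
package's standing test conditions: overdispersion and library-size
spread in the range routinely estimated for single-cell data, marker
blocks strong enough to be biologically plausible but far from
noiseless. These sizes also keep the full test suite and the acceptance
script in the seconds-to-minutes range. What the simulator does **not**
emulate: doublets, ambient RNA, batch effects, correlated marker
programs shared between related types, or realistic gene-length effects
(counts are length-free, which is why the signature builder works in
CPM, not TPM). Passing the recovery checks therefore demonstrates
correctness of the estimators under a clean generative model, not
performance on real tissue.

# What the recovery protocol shows

The headline property — simulate 20 pseudo-bulk samples, build a
signature and marker sets from the same reference with
`buildSignatureFromSC` (markers ranked by fold over the **maximum** of
the other types' means, stricter than fold-over-mean so a gene shared by
two types can mark neither; ties broken lexicographically for
determinism), then deconvolve and benchmark — is computed by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`. Under
these conditions the fraction engines and the median-marker engine
recover per-type composition with high per-type Pearson correlation and
low RMSE, while the signed-rank engine tracks composition strongly in
rank terms but falls short of the same Pearson bar: with 200 of 2000
genes being markers, the mean normalized rank of a type's markers
saturates toward its upper bound as the type's fraction grows, a concave
response that caps the *linear* correlation however well the ordering is
preserved. This is a property of the rank statistic itself, documented
here rather than patched away; treat signed-rank scores as ordinal
between samples.

# Benchmarking conventions

`evaluateDeconvolution` correlates estimate against truth **per cell
type across samples** (matching how deconvolution assessments are
usually displayed; a per-sample mode across types is available via
`perSample = TRUE`). RMSE is computed for fraction results only — scores
live on arbitrary scales, so an RMSE against fractions would be
meaningless. A correlation needs at least 3 paired samples (2 points
always give $\pm 1$) and non-zero truth variance; anything else is
reported as `NA` with a flag rather than a number. Missing estimates are
dropped pairwise.

# Known limitations

* The bundled resources are structural stand-ins; serious analyses
  should supply study-specific signatures via `readSignature`/`readGMT`
  or build them from annotated single-cell data.
* Signed-rank scores saturate at extreme compositions (above).
* Unknown-content estimation is only identifiable when the missing cell
  types actually express genes outside (or orthogonally to) the
  signature span on the shared genes.
* The ortholog mapper matches plain symbols; Ensembl-ID inputs and
  paralog-aware disambiguation are out of scope.
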