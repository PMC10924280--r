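Package: murideconv
Title: Cell-Type Deconvolution of Mouse Bulk RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the cellular composition of murine tissues from bulk
    RNA-seq expression matrices. Implements the main algorithmic families used
    for immune-cell deconvolution: median marker-gene scoring, signed
    rank-based gene-set scoring, constrained least-squares deconvolution with
    optional estimation of uncharacterized cellular content, nu-support-vector
    regression, and repeated-subsampling elastic-net regression. Ships a
    mouse-to-human orthologous gene mapping layer so human-trained signatures
    apply to murine data, a signature builder for labeled single-cell counts, a
    negative-binomial single-cell simulator with pseudo-bulk construction and
    known ground-truth fractions, a cell-type nomenclature harmonization and
    fine-to-major grouping layer, and per-cell-type benchmarking (Pearson
    correlation and RMSE) against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    pracma,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, RNASeq, ImmunoOncology, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
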