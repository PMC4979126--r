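Package: benfordexpr
Title: Benford First-Digit Analysis of Digital Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores genes and samples in RNA-seq expression matrices by their
    deviation from the Benford first-significant-digit law using a mean
    absolute error (MAE) conformity statistic. Provides CPM/RPKM/TPM
    normalization, an expressed-gene filter, gene-centric and
    individual-centric MAE scoring with ranking and threshold selection,
    KNN prediction of tissue-specific versus housekeeping status from
    Benford-derived features with multidimensional-scaling visualization,
    and a lognormal synthetic expression generator emulating the dynamic-range
    structure of housekeeping and tissue-specific genes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
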