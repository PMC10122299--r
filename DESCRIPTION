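Package: rootstockGxE
Title: Rootstock-by-Environment Analysis of Grafted-Scion Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Variance-partitioning selection of rootstock-responsive genes,
    self-organizing-map clustering of their expression profiles,
    windowed composite statistics of on-site weather with an environmental
    principal component analysis, a double-PCA (expression by environment)
    interaction screen with Tukey post-hoc slope contrasts, and
    hypergeometric functional-term enrichment, for replicated multi-year
    grafted-vineyard transcriptome studies. Includes median-of-ratios
    normalization with a parametric dispersion trend and closed-form
    variance-stabilizing transform, and a negative-binomial study simulator
    with planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    emmeans,
    mclust,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
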