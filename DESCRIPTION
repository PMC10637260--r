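Package: scmeta
Title: Expression-Diversity and Age-Trend Meta-Analysis for Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting exposure groups in multi-sample single-cell
    RNA-seq atlases. Implements a per-cluster expression-diversity statistic
    based on normalized closeness centrality of cell-cell correlation graphs
    (VARIED), a pseudobulk age-regression slope-difference procedure (AGED),
    control-binned gene-set module scoring, quality-control filtering,
    log-normalization, Welch group contrasts of cell composition and gene
    expression, and a ground-truthed synthetic atlas generator for validating
    every stage without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
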