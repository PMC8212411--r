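Package: cytocrosstalk
Title: Cytokine-Receptor Cross-Talk Discovery from Single-Cell Progenitor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies condition-specific cytokine-receptor signalling axes
    between tumours and bone-marrow hematopoietic stem and progenitor cells.
    Provides a synthetic single-cell count simulator with planted ground
    truth, quality-control filtering and log-normalization, reference-based
    cell-type annotation by Spearman correlation with a chi-squared outlier
    test, a bias-corrected and accelerated (BCa) bootstrap test for
    cell-type proportion shifts between two conditions, per-cell-type
    Wilcoxon rank-sum differential expression with fold-change and detection
    filters, and the pairing and ranking of secreted factors with their
    differentially expressed receptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
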