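Package: camnet
Title: Multi-Omics Integration and Functional-Module Network Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating transcriptome, proteome and metabolome
    feature tables under a grouped experimental design: the standard
    metabolomics quality-control cascade (presence filtering, minimum
    imputation, sum normalization, pooled-QC relative-standard-deviation
    filtering, log10 transformation), PLS-DA variable importance in
    projection (VIP) scores, per-layer differential-feature calling with
    fold-change, t-test, FDR and VIP rules, over-representation and
    pre-ranked gene-set enrichment statistics, and the contraction of a
    differential protein-protein interaction network into a quotient graph
    over KEGG pathway modules ranked by connectivity degree. A synthetic
    multi-omics generator with planted ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse,
    yaml
Config/testthat/edition: 3
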