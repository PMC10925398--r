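Package: hepnet
Title: Heparin-Enriched Plasma Proteomics with Brain Network Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-batch tandem-mass-tag (TMT) plasma
    proteomics with pooled internal standards: channel-sum normalization,
    missingness filtering, iterative median-polish batch correction anchored
    on global internal standard (GIS) channels, bootstrap covariate
    regression, two-group differential abundance with Benjamini-Hochberg
    control, Fisher combined-probability meta-analysis across sample sets,
    protein-biomarker trait correlation, and projection of a plasma proteome
    onto a reference brain co-expression network via biweight midcorrelation
    (kME) with module, cell-type and gene-set overrepresentation tests. A
    synthetic-data module generates TMT studies, reference networks and
    label-free fraction experiments with known ground truth so that every
    stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
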