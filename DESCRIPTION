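Package: opnsplice
Title: Exon-Level Deconvolution and qPCR Quantification of Osteopontin
    Splice Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for demonstrating co-overexpression of the five
    osteopontin (SPP1/OPN) splice isoforms (OPNa, OPNb, OPNc, OPN4, OPN5)
    in tumor cohorts from exon-level expression data. Builds exon-isoform
    incidence matrices, determines which isoform groups are identifiable
    from an observed exon set, estimates identifiable group abundances by
    successive subtraction or non-negative least squares, correlates group
    abundances with total gene expression, predicts isoform-specific
    RT-PCR amplicon lengths, and implements multi-reference-gene 2^-ddCt
    quantification with a "2-fold plus one standard deviation"
    overexpression caller and a single-tube copy-number ratio. A seeded
    synthetic-cohort generator emulates the assumed statistical structure
    (shared-factor co-overexpression, exon probe signals, Ct tables) so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    yaml,
    jsonlite,
    withr,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
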