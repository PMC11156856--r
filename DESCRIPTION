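Package: paracre
Title: Cis-Regulatory Analysis of Paralogous Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cis-regulation across recently expanded
    paralogous gene families whose near-identical sequences defeat standard
    genomics pipelines. Implements consensus-coordinate projection of
    epigenomic signal across paralogs, rescue of multimapping reads by
    normalized alignment score, ATAC-seq Tn5 insertion pileups and
    element-level quantification, CAGE-style TSS filtering, power-law
    normalization and two-step tag clustering with cap-signature filtering,
    binarized single-cell co-expression odds ratios with Fisher exact tests
    and FDR control, matched-background Hi-C contact enrichment, and
    conserved-element, motif (PWM with exact p-values) and direct/inverted
    homology scanning. Includes synthetic-data generators that emulate a
    duplicated gene family with planted regulatory elements, so every
    analysis can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Biostrings,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
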