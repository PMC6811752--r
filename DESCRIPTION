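Package: pancrosstalk
Title: Compartment Crosstalk Inference from Bulk RNA-seq of Microdissected Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers ligand-receptor crosstalk between two microdissected tissue
    compartments (such as the embryonic dorsal pancreatic bud and its surrounding
    mesenchyme) from bulk RNA-seq read counts. Implements counts-per-million
    normalization, common negative-binomial dispersion estimation by conditional
    maximum likelihood, a conditional exact test for two-group differential
    expression with Benjamini-Hochberg correction, a replicate-variability and
    control-gene flowchart for marker selection, hypergeometric Gene Ontology
    over-representation, and a three-criterion priority score that ranks
    cross-compartment interacting pairs of secreted and cell-surface gene
    products. Includes a negative-binomial simulator with planted ground truth
    for end-to-end validation, and helpers for qPCR relative quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
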