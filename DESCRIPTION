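Package: pocketbench
Title: Benchmarking Toolkit for Protein Binding-Pocket Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates benchmark datasets of protein-ligand binding pockets,
    computes similarity and alignment-quality statistics for pocket-matching
    methods (contact-overlap coefficient, Kendall tau ordinal association of
    alignments, Spearman rank correlation of virtual-screening results,
    ligand RMSD upon pocket superposition, alignment Matthews correlation),
    performs ROC analysis of pocket-pair classifiers, and combines direct
    alignment scores with screening rank correlation into a multiplicative
    meta-predictor.  Ships deterministic synthetic-data generators (toy
    complexes with planted pockets, alignments with controlled sequence
    order, rank matrices with planted correlation) so every component is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
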