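Package: dismotif
Title: Exhaustive Discriminative IUPAC Motif Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discovers degenerate DNA motifs over the 15-letter IUPAC
    alphabet that are over-represented in a positive (signal) sequence set
    relative to a negative (control) set. All IUPAC motifs of a fixed
    length whose exact instances are all present in the positive set are
    organised in a motif lattice, scored by mutual information on
    sequence-level presence/absence contingency tables, reduced to
    dominant non-dominated motifs, and ranked with one-sided Fisher exact
    tests under Holm-Bonferroni correction. Secondary motifs are found by
    masking instance closures directly in the lattice, and overlapping
    motifs found in scanning mode can be clustered around high-information
    references. A synthetic benchmark module generates uniform random
    sequence sets with implanted IUPAC motifs of controlled degeneracy and
    scores predictions with the nucleotide-level correlation coefficient
    (nCC) and specificity (SPC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
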