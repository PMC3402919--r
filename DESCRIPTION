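Package: fuzzytr
Title: Fuzzy Tandem Repeat Detection in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ab-initio detection of fuzzy (highly divergent) amino-acid
    tandem repeats in protein sequences.  Converts BLOSUM similarity
    matrices into a normalized weighted edit distance, seeds candidate
    periods with a complete family of gapped q-grams under a similarity
    ranking, ranks periods by anti-smear and multiplicity weighting,
    localizes candidates by positional k-density, validates repeats
    against a weighted Steiner consensus criterion, and assesses
    significance of detected repeats with a shuffle-based Wilcoxon
    signed-rank procedure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
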