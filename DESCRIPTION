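Package: contextmerge
Title: Context-Aware Merging of Overlapping Paired-End Sequencing Reads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges the forward and reverse reads of overlapping paired-end
    sequencing fragments into virtually elongated reads. The best overlap is
    located by minimum mismatch ratio; mismatching bases inside the overlap
    are resolved by Phred quality scores when the score difference is
    decisive, and otherwise by a majority vote over k-mer context windows
    looked up in an exact k-mer count table built from the whole input.
    Designed for high-coverage amplicon data, where the k-mer table is highly
    informative. Ships a paired-end amplicon read simulator with
    position-dependent substitution errors and matching per-base qualities,
    plus evaluation metrics (accuracy, precision, recall, F1) against
    simulated truth, so the whole method can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
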