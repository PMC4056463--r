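Package: splitmap
Title: Split-Read Alignment and Junction Discovery for Single-End RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps single-end cDNA reads across multiple genomic loci and
    strands to detect conventional splice junctions as well as
    strand-reversing (trans-splicing), long-range (fusion) and circular
    (back-splice) junctions.  Reads are seeded with entropy-filtered
    suffix-array matches, seeds are joined by a greedy score-based chaining
    step, and the chained loci are stitched by a Smith-Waterman-like local
    transition alignment that allows penalized jumps between loci.  The
    package also ships a spliced-read simulator with Illumina- and 454-style
    error models and ground-truth junction tables, and an evaluator that
    reports junction recall and false-positive rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
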