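Package: miRcurate
Title: Compile, Select, and Curate Plant miRNA Annotations from Small RNA Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aggregates candidate microRNA (miRNA) precursor loci from
    multiple annotation sources and small RNA sequencing read alignments,
    scores them against hairpin-structure, duplex-geometry and
    read-expression criteria together with a one-class support vector
    machine, and produces curation-ready summaries including isomiR
    classification, arm-switching detection, genomic-context assignment and
    polyploid subgenome/homoeolog analytics. Includes a deterministic
    synthetic-fixture generator (planted hairpins with known mature/star
    coordinates, shuffled decoys, multi-sample read stacks) so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
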