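Package: mirpipe
Title: Small RNA-Seq miRNA Discovery, Profiling and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible re-implementation of a classic
    two-library small RNA sequencing workflow: adapter trimming and read
    accounting, exact genome mapping of unique tags, hierarchical annotation
    against ncRNA/repeat/exon/intron features, known-miRNA profiling with
    isomiR end variants and single-base (seed-aware) edits, hairpin-based
    novel miRNA prediction driven by a built-in nearest-neighbour RNA folding
    engine and the minimal free energy index (MFEI), count-based differential
    expression between two libraries with an exact conditional test, and
    rule-based miRNA target prediction with G:U wobble scoring. Ships a
    synthetic-data generator that plants ground truth (hairpins, isomiRs,
    edits, fold changes) so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    graphics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
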