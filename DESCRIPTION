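Package: VariantSweep
Title: Sweep-Line Annotation of Genetic Variants with Whole-Genome Feature Tracks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating large lists of genetic variants with
    whole-genome feature tracks. Provides a compact delta-varint codec for
    million-scale variant position lists, a sorted on-disk feature store with
    a per-chromosome pointer directory for direct access, and two linear-time
    sweep-line (sort-merge) join algorithms: exact-location overlap and
    flanking-window overlap up to 1 Mb. Numeric feature signals are summarized
    per variant as window means and genome-wide mid-rank percentiles, and
    results are written as tab-delimited annotation tables. Includes seeded
    synthetic-data generators (genome models, variant lists, feature tracks,
    planted-truth join instances) and a quadratic brute-force join oracle for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    GenomicRanges,
    IRanges,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: VariantAnnotation, Annotation, DataImport, Software
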