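Package: rarecnv
Title: Rare Copy-Number Variant Detection and Association from SNP-Array
    Intensity Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality control, batch correction and rare copy-number variant
    (CNV) analysis for dense SNP-array intensity data. Provides marker- and
    sample-level QC on Log-R-ratio (LRR) and B-allele-frequency (BAF) signals
    (call rates, exact Hardy-Weinberg tests, derivative log-ratio spread,
    GC wave factor, whole-chromosome aberration screens, plate exclusion),
    principal-component correction of batch structure, a five-state hidden
    Markov model caller with distance-dependent transitions, fragment merging
    and posterior quality scores, copy-number-variable-region (CNVR)
    construction with segment-group semantics, and the full association
    layer: case-control burden by length strata, regional Fisher exact
    scans, family transmission counts, exact transmission-disequilibrium
    tests, de novo vetting against parental intensity evidence, and power
    grids. A seeded synthetic-data generator emulates plate/cohort offsets,
    GC-correlated waves, latent batch components and spiked CNVs so that
    every stage is testable without access to raw genotyping data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
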