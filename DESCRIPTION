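Package: dsrnatk
Title: Analysis Toolkit for Double-Stranded RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processes strand-specific sequencing libraries that enrich for
    base-paired (double-stranded) RNA. Collapses and adapter-trims raw reads,
    classifies mapped reads against a hierarchical annotation, scores
    sense/antisense strand bias, calls unusually long read-covered segments
    ("hotspots") with a per-chromosome geometric length model, performs 1 kb
    differential window analysis between libraries to nominate RNA-dependent
    RNA polymerase substrates, detects 21-nt phased siRNA production with a
    hypergeometric register test, compares per-base conservation of hotspots
    against flanking sequence, and builds read-coverage-constrained RNA
    secondary structure models (constrained Nussinov engine built in, RNAfold
    adapter optional). Includes a deterministic synthetic-data generator with
    truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
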