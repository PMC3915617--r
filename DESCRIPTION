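Package: rangestore
Title: Bulk-Insert-Optimised Embedded Storage for Position-Specific Genomic Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embedded, order-preserving key-value storage engine for
    position-specific DNA-related records: fixed-width record schemas with an
    order-preserving big-endian binary codec, range-partitioned in-memory
    buffering, mergesort-based synchronisation of sorted runs with sparse-indexed
    chunked bucket files on disk, fast single lookups and streaming range selects
    with optional value filtering. Includes built-in schemas for SNP tables in
    the 1001-Genomes style and BLAST tabular hits against retroviral fragments,
    importers for both formats, a seeded synthetic record generator, an
    in-memory reference oracle, and a desk-scale benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    readr,
    withr,
    ggplot2,
    generics,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
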