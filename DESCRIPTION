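Package: linkexome
Title: Two-Point Linkage Analysis and Exome Variant Filtering for
    Dominant Disease Gene Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact two-point parametric linkage analysis on loop-free
    pedigrees by Elston-Stewart peeling under a configurable single-locus
    autosomal dominant disease model, with LOD-score curves, recombination
    fraction estimation, and definition of the linked interval from flanking
    markers.  Couples the linkage results to an exome variant prioritisation
    pipeline: post-calling quality filters, functional-class filtering,
    subtraction of database and control variant sets, intersection across
    affected individuals, restriction to the linked interval, codon-level
    amino-acid annotation and family co-segregation checking.  Includes a
    gene-dropping simulator and exome-table generator so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
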