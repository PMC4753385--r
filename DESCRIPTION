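Package: poolcnv
Title: Window-Based Copy-Number Analysis of Low-Coverage Pooled DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting chromosomal gains and losses from
    low-coverage whole-genome sequencing of pooled tumor DNA. Generates an
    in-silico reference read set by uniform random sampling of the genome,
    filters reads by quality, sequence complexity and mapping uniqueness,
    counts mapped reads in fixed-length (default 40 kb) windows, computes
    per-window log2 sample/reference ratios, summarises whole-chromosome
    integrity as reads per kilobase with linearity diagnostics, calls
    loss/gain segments and intersects them across pools, annotates calls
    with cytogenetic bands, and renders banded chromosome ideograms with
    the log2 track as deterministic SVG. Includes a synthetic-data
    generator producing toy genomes, cytoband tables and pooled read sets
    with engineered copy-number events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    rlang,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
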