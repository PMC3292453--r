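Package: tedyn
Title: Comparative Transposable Element Annotation and Insertion-Age Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-scale pipeline for comparing transposable-element (TE)
    abundance and insertion-age dynamics between two related genomes, such as a
    predominantly selfing species and its outcrossing relative. Covers de novo
    repeat-family discovery by l-mer seeding and consensus extension, candidate
    filtering and redundancy merging against a known library, rule-based class
    assignment, homology annotation of individual copies with per-copy
    alignments, nearest-neighbour insertion dating via T = K/(2r) with
    Jukes-Cantor corrected divergences, shared/unique family partitioning with
    rank-based copy-number comparisons, exponential age-distribution fitting
    with half-life reporting, and detection of a recent insertion deficit.
    Includes a two-lineage coalescent-style genome simulator with complete
    per-copy truth records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
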