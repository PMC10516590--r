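Package: condelscan
Title: Screening Pairwise Whole-Genome Alignment Chains for Conserved
    Sequence Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics screen that identifies conserved
    sequence deletions (CONDELs): reference-genome intervals that are
    deeply conserved in trait-complete outgroup species yet recurrently
    deleted in independent trait-reduced target lineages. Implements UCSC
    chain-format parsing, chain-gap deletion calling with assembly-gap
    masking, multi-scale sliding-window conserved-element detection under
    a genome-wide coverage quota, an orthology-confidence filter, the
    per-gene association scan with clade-consensus deletion calling, and
    the accompanying statistics (Boschloo's unconditional exact test,
    Welch's t, Mann-Whitney U, phylogenetic generalized least-squares
    means, patristic distances, and position-weight-matrix scanning).
    Includes a seed-reproducible synthetic-data generator that plants
    conserved elements and clade-specific deletions so the full screen
    can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    ape,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
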