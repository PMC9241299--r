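Package: icrscan
Title: Genome-Wide Prediction of Candidate Imprinting Control Regions from
    ZFP57 Binding-Site and Composite-Motif Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates candidate Imprinting Control Regions (ICRs) in genomic
    DNA by exact-match scanning of chromosome sequences for ZFP57 binding
    sites and CpG-rich composite motifs (ZFBS-morph overlaps), computing the
    density of composite-motif occurrences with an 850-base sliding window,
    suppressing isolated occurrences as background noise, and calling tiered
    density peaks. Emits UCSC genome browser custom tracks (BED and bedGraph)
    reproducing the three-track display (binding sites dense, composite
    motifs pack, density peaks full). Includes a seeded synthetic-genome
    generator with planted motif clusters and exact ground truth, a recovery
    evaluator, and a benchmark harness scoring called peaks against a panel
    of reference ICR intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
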