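Package: rtsig
Title: Reverse-Transcription Signature Profiling and Modification
    Candidate Screening for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts mapped RNA-Seq reads (SAM) or samtools-style pileup
    text into per-position reverse-transcription (RT) signature profiles:
    coverage, mismatch rate and base composition, read-start (arrest) rate,
    and the context-sensitive arrest rate (CSA), the fold change of a
    site's arrest rate over the median arrest rate of its sequence
    neighbourhood.  Profiles are stored in a block-file layout with fast
    region access, summarised per reference (coverage peak, counts of
    high-arrest, high-mismatch and heterogeneous-mismatch sites), screened
    for modification candidates with user-defined Boolean threshold
    formulas and exact binomial site tests under Bonferroni or
    Benjamini-Hochberg correction, and compared between samples
    (e.g. untreated versus chemically treated) with per-position deltas
    and Fisher tests.  Includes a seeded read simulator that plants
    mismatch and arrest signatures for end-to-end validation, batch
    plotting with above-threshold markers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    methods,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
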