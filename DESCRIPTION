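Package: splicetyper
Title: Detection, Typing and Summarisation of Alternative Splicing Events
    from Transcript Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and types alternative splicing (AS) events by comparing
    observed transcript exon chains against a reference gene annotation.
    Events are classified as exon skipping (ES), intron retention (IR),
    alternative donor (AD), alternative acceptor (AA) or alternative
    position (AP), and called conserved or novel against the gene's
    annotated isoforms. Includes a synthetic transcript-structure simulator
    with full ground truth, descriptive summaries (events-per-variant bins,
    event-type frequencies, Venn partitions of experimental groups,
    cross-species sharing), hypergeometric term over-representation with
    Benjamini-Hochberg FDR control, and a configured end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
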