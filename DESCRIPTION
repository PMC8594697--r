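Package: methylgraft
Title: Replicate-Aware Sliding-Window DMR Calling and Methylation-Transcription Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from replicated
    whole-genome bisulfite methylation-call tables using 200-bp sliding
    windows, per-window replicate tests with a standard-deviation-of-averages
    (SDA) reproducibility filter, and context stratification (CG/CHG/CHH).
    Associates DMRs with genes and transposable elements within a flanking
    distance, classifies promoter/body/terminator position, selects
    differential transcripts, computes functional-bin enrichment with
    Benjamini-Hochberg correction, joins methylation with transcription and
    tests their correlation, and provides relative qPCR quantification
    (2^-ddCt) with multi-reference-gene normalization. Ships a seeded
    synthetic bisulfite methylome simulator with injected DMRs and coupled
    expression so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
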