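Package: strinit
Title: Transcription Initiation at Short Tandem Repeats from 5'-End Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcription initiation at short tandem repeats (STRs)
    from strand-specific CAGE-like 5'-end coverage, scores transcriptional
    directionality, validates capped 5' ends through first-base G mismatches,
    trains small convolutional sequence-to-signal models on windows centered at
    STR 3' ends, interprets them by first-layer filter ablation and in-silico
    mutagenesis, and tests sign concordance between predicted allele effects
    and eQTL slopes. A self-contained synthetic-data generator with a
    closed-form sequence-to-signal function provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
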