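Package: stressxtalk
Title: Cross Talk Between Cytokine- and Heat-Shock-Driven Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of cross talk between TNF-alpha/NF-kB- and
    heat-shock/HSF1-driven transcription. Provides factorial
    differential-expression calling with a moderated t statistic and Storey
    q-values, log-odds PWM scanning of proximal promoters for kB and
    heat-shock-element motifs, assignment of HSF1 ChIP-seq peaks to
    strand-aware regulatory windows with a simple Poisson peak caller,
    classification of genes into combined-effect (interaction) modes,
    hypergeometric term-overrepresentation statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
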