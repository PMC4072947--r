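Package: txwave
Title: Transcription Wave Detection and Elongation-Rate Estimation from
    Nascent RNA Coverage
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of nascent-RNA sequencing time courses following
    release of a reversible transcription-elongation block (DRB/4sU
    labeling designs). Builds normalized 100-bp binned coverage from
    aligned reads or bedGraph tracks, extracts strand-oriented intronic
    signal per gene, detects the advancing transcription-wave front in
    each post-release sample by comparison to the pre-release profile
    followed by derivative-based refinement, combines replicate fronts
    into per-gene Pol II elongation rates (kb/min) with confidence
    intervals and delay times, and infers relative transcription
    initiation frequencies from the linear decay of the wave signal.
    Includes a generative simulator with known per-gene parameters so
    the whole pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Transcriptomics, Sequencing, Coverage, GeneRegulation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
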