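Package: snoguard
Title: C/D-Box snoRNA Target Prediction and tRNA Fragmentation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how C/D-box small nucleolar RNAs guide
    2'-O-ribose methylation of transfer RNAs and thereby modulate
    site-specific tRNA fragmentation. Provides antisense-element
    extraction and snoRNA:tRNA duplex prediction with placement of the
    predicted methylation site, small-RNA read assignment and
    tRNA-derived fragment (tRF) profiling with RPM normalisation,
    estimated-methylated-fraction (EMF) computation from low-dNTP
    reverse-transcription qPCR (RTL-Q) cycle thresholds, the qPCR
    expression indices used in fragmentation studies, and a synthetic
    data generator that emulates methylation-dependent site-specific
    cleavage so every pipeline stage is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
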