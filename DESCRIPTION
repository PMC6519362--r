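Package: msiscope
Title: Low-Level Microsatellite Instability Scoring for Constitutional
    Mismatch Repair Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects low-level microsatellite instability (MSI) in
    peripheral-blood-leukocyte DNA to support the diagnosis of constitutional
    mismatch repair deficiency (CMMRD). Reads carrying molecular barcodes
    (UMIs) from a targeted panel of 24 short monomorphic mononucleotide
    repeats are assigned to markers by flank anchoring, grouped into UMI
    families, and consensus repeat lengths are called to suppress polymerase
    slippage noise. Per-marker wild-type read frequencies are modelled across
    a control cohort with Beta distributions; sample frequencies are converted
    to lower-tail probabilities, combined with Fisher's method, and reported
    as a -log10 score with 5% and 1% classification thresholds. Includes a
    synthetic-data generator (frequency tables and UMI-bearing FASTQ) so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
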