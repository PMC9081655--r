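Package: cwmyb
Title: Identification, Classification and Expression Screening of Plant MYB
    Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for annotating a plant MYB transcription
    factor family from protein sequences: degenerate detection of the ~52
    residue MYB "R" repeats (R2 consensus W-x19-W-x19-W, R3 consensus
    [FILM]-x18-W-x18-W), subfamily assignment (R2R3, 3R, 4R, MYB-related)
    with signature-motif typing of the MYB-related class (CCA1-like, R-R,
    TBP-like, Myb-CC, GARP-like), EAR (LxLxL) repression-motif annotation,
    greedy redundancy removal at a sequence-identity cutoff, theoretical
    isoelectric point (Bjellqvist pKa set) and average molecular weight,
    TPM-based differential expression screening, and relative qPCR
    quantification by the comparative 2^-ddCt method. Ships a synthetic-data
    module that plants repeats, motifs, fold changes and Ct shifts with known
    truth labels so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
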