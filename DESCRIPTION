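Package: peelpaste
Title: Design and Simulation Toolkit for Retargeting IS608-Family
    Single-Stranded DNA Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs engineered left-end/junction single-stranded DNA
    sequences that direct IS608 (IS200/IS605 family) transposon integration
    to user-chosen 12-17 nt target sites by extended base pairing with the
    target. Predicts single-stranded DNA secondary structure by weighted
    base-pair maximization to detect and open occluding hairpins, scans
    sequences for candidate TTAC integration sites, scores target versus
    off-target selectivity with a cooperative competition model calibrated
    to in vitro strand-transfer outcomes, and simulates the sequence
    bookkeeping of every peel-and-paste transposition step, rendering
    product lengths as a virtual gel. Includes seeded generators for
    synthetic transposon ends, junctions, donors and target oligo pools so
    all analyses run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
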