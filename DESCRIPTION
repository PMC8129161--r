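Package: rngtask
Title: Randomization and Recurrence Measures for Random Number Generation Tasks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores performance on the Random Number Generation (RNG) task and
    other categorical response sequences. Implements the thirteen classical
    randomization measures (Redundancy, RNG and RNG2 digram indices,
    Null-Score Quotient, Coupon score, first-order differences, Adjacency,
    Turning Point Index, Phase Lengths, Runs, Repetition Distance, Repetition
    Gap, and Phi indices) in both the classical percentage convention and a
    modernized proportion convention, together with auto-recurrence
    quantification analysis (RQA) for nominal sequences: recurrence rate,
    determinism, laminarity, and diagonal/vertical line-length statistics with
    exact-match recurrence. Includes a deterministic sequence generator and
    constrained fixture constructors, a brute-force RQA reference
    implementation for verification, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
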