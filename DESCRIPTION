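Package: guidecraft
Title: Genome Arithmetic, Off-Target Counting and Prime-Editing Design for
    CRISPR Guide RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design CRISPR/Cas9 guide RNAs for applications that target one
    locus or thousands at once. Provides a stranded genome-arithmetic
    vocabulary (extend, flank, cut-site expansion) that turns target ranges
    into spacer search regions, N20-PAM spacer discovery on both strands,
    genome-wide k-mismatch off-target counting with two engines (an exhaustive
    window scan and a pigeonhole seed-and-verify matcher), target-set-specific
    filtering that distinguishes cross-target matches from true off-targets,
    PE2/PE3 prime-editing reagent construction (editing spacers, primer
    binding site, reverse-transcription template, nicking spacers), pluggable
    on-target scoring, and a seeded synthetic-genome generator for fully
    offline testing. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
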