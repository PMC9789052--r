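Package: ntescan
Title: Detection and Comparative Scoring of Non-AUG N-Terminal Proteoform Extensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering N-terminally extended proteoforms that
    initiate at non-AUG (near-cognate) start codons upstream of annotated
    coding sequences. Extracts theoretical in-frame upstream extensions from a
    transcript annotation, detects and ranks actively translated extensions
    from ribosome-profiling P-site profiles using triplet-periodicity
    statistics, scores the same regions for protein-coding evolutionary
    signatures from reference-anchored multiple genome alignments, builds
    rule-based gene sets (ribosome-profiling-supported, conservation-supported
    and untranslated-control sets), and computes the comparison statistics
    between the two evidence types. Includes a fully seeded synthetic-data
    generator that emits every input dialect the pipeline consumes together
    with ground truth, plus translation-initiation-site context scoring and
    windowed RNA-structure scanning for called starts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
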