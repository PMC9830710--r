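Package: chromanchor
Title: Reference-Guided Pseudo-Chromosome Anchoring and Rearrangement
    Artifact Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how reference-guided pseudo-chromosome
    reconstruction can erase or fabricate chromosomal rearrangements.
    Implements an exact-match seed and monotonic-chain alignment core,
    chimeric-scaffold detection and splitting, greedy best-first placement
    of scaffolds onto reference chromosomes with AGP bookkeeping, a
    chain-based structural-variant caller (synteny, inversion,
    translocation, duplication), breakpoint-provenance classification with
    mate-pair linkage support, and a truth-tracked genome simulator with
    planted rearrangements for end-to-end evaluation of anchoring
    reference bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
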