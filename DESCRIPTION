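Package: trimscan
Title: Discovery and Structural Annotation of TRIM and TRIMp3 Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover terminal-repeat retrotransposons in miniature
    (TRIMs) in genome assemblies and annotate their defining structure: the
    long terminal repeat (LTR) pair, target site duplication (TSD),
    primer-binding site (PBS) typed by tRNA complementarity, polypurine tract
    (PPT), and internal RNA polymerase III promoter motifs (tRNA-type box A /
    box B, or 5S-type box A / IE / box C). Families carrying a small-RNA-derived
    pol III promoter in their LTRs are classified as TRIMp3, others as TRIMp2.
    Includes seeded genome scanning, single-linkage family clustering at 75
    percent coverage / 75 percent identity, 50 percent majority-rule consensus
    building with iterative flank extension to the element termini, solo-LTR
    detection, full-length copy counting, Jukes-Cantor/BioNJ phylogenies with
    bootstrap supports, and a synthetic-genome generator that plants elements
    with a complete truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
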