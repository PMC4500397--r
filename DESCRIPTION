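Package: gvcompare
Title: Comparative Genomics of Granulovirus (Betabaculovirus) Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of circular double-stranded DNA
    baculovirus genomes, built around the workflow used to characterize newly
    sequenced granulovirus (betabaculovirus) isolates. Provides circular-genome
    input/output and coordinate arithmetic, six-frame methionine-initiated ORF
    annotation with a minimal-overlap selection rule and granulin-anchored
    numbering, exact affine-gap protein alignment for reciprocal-best-hit
    ortholog mapping and gene-class assignment against reference panels (core,
    lepidopteran-shared, betabaculovirus-specific), gene parity plots with
    collinearity scoring and inversion detection, discovery of non-hr repeat
    regions (tandem imperfect direct repeats, imperfect palindromes, AT-rich
    context) with Nussinov-style hairpin prediction, early/late promoter motif
    scanning, a concatenated core-protein distance phylogeny with bootstrap
    support, and a synthetic-genome simulator with full planted truth tables so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
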