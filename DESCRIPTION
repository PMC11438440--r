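Package: mitoskim
Title: Mitogenome Reconstruction and Species Identification from Nanopore Genome Skims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for shallow whole-genome shotgun ("genome skim") Oxford
    Nanopore data from non-model vertebrates. Recruits mitochondrial reads from
    noisy long-read runs with a seeded, gapped local aligner using blastn-style
    scoring and Karlin-Altschul E-values; reconstructs the circular mitogenome by
    reference-guided pileup consensus or a minimal de novo overlap assembler, with
    iterative consensus polishing and depth profiling; projects reference gene
    annotations onto assemblies and classifies every gene into hit/error
    categories gated on open reading frames under the vertebrate mitochondrial
    code; identifies species from raw recruited reads against taxonomically
    scoped databases with explicit e-value/identity hit ranking; and drives the
    full data-type by assembler benchmark grid. A simulator generates annotated
    mitogenomes and ONT-like skim runs with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
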