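Package: synkaryo
Title: Comparative Synteny and Karyotype Rearrangement Analysis for
    Holocentric Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing chromosome-level genome assemblies of
    holocentric organisms (such as satyrine butterflies) from pairwise
    whole-genome alignments in PAF format. Filters alignment blocks by
    mapping quality and length, infers chromosome-level homology
    (one-to-one synteny, fusions, fissions), calls inversions as maximal
    reversed-orientation block runs, detects neo-Z sex chromosomes formed
    by Z-autosome fusion, and polarizes rearrangement events onto a
    three-taxon phylogeny. Includes a karyotype-evolution simulator that
    plants fusions, fissions and inversions along a species tree and
    emits realistic fragmented alignments with ground-truth logs, so the
    whole pipeline can be validated offline, plus dot-plot, ideogram and
    circular synteny visualisations.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
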