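Package: musaic
Title: Chromosome Ancestry Painting and Divergence Dating for Mosaic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid plant genomes that are segmental
    mosaics of several ancestral (sub)species, as in cultivated bananas.
    Discovers short diagnostic sequence tags specific to each ancestral
    group, paints chromosome assemblies with windowed ancestry labels,
    phases markers from parent-child trios and parses contigs into
    haplotypes, chains gene anchors into collinear synteny blocks and
    builds synteny-anchored ortholog groups, estimates synonymous
    divergence (Ks) with the Nei-Gojobori (1986) counting method, dates
    divergences with a molecular clock, and summarises gene-tree support
    for the branches of a species tree. A self-contained simulator
    generates ancestral panels, mosaic assemblies, trios, chromosome
    rearrangements and codon alignments with known truth, so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
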