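Package: mercmags
Title: Screening, Validation and Expression Profiling of Mercury-Cycling
    Genes in Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genome-resolved workflow for identifying mercury-cycling
    genes (the hgcAB mercury-methylation pair, the mercuric reductase
    merA, and the organomercury lyase merB) in metagenome-assembled
    genomes (MAGs), and for profiling their expression from
    metatranscriptomic coverage. Candidates are found by position-specific
    log-odds profile scoring with family-specific e-value thresholds,
    then curated the way genome-resolved studies curate them: hgcA calls
    require an hgcB gene immediately downstream on the same strand, MerA
    calls require the essential catalytic and metal-binding cysteine
    pairs (homologs lacking them are reported as merA-like), and MerB
    calls require the conserved C96/D99/C117/C159 signature mapped
    through a global alignment to a reference protein. Transcript
    coverage is normalized per bin to the housekeeping RNA polymerase
    subunit B (rpoB) gene, MAG coverage is summarized as a
    relative-abundance proxy, and a seeded synthetic-community generator
    with planted ground truth makes the whole pipeline testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
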