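#' Packaged synthetic reference proteins
#'
#' The package ships deterministic *synthetic* stand-in reference proteins
#' for each screened family (`hgcA`, `hgcB`, `merA`, `merB`, `rpoB`). They
#' are random-composition sequences that carry the field's diagnostic
#' residues at the canonical reference coordinates: the MerB organomercury
#' lyase signature (Cys96, Asp99, Cys117, Cys159), the MerA mercuric
#' reductase active-site cysteine pair (136/141) and C-terminal metal-binding
#' pair (558/559) on a 561-residue stand-in, a cap-helix-like motif in HgcA
#' and ferredoxin-like CXXC motifs in HgcB. They anchor signature coordinates
#' and profile construction; they are not biological sequences, and real
#' references can be substituted wherever a reference is accepted.
#'
#' @param family Optional family name; if given, the single reference
#'   sequence is returned as a one-element named character vector.
#' @return Named character vector of protein sequences (names like
#'   `merA_ref`).
#' @export
#' @examples
#' nchar(ref_proteins("merB"))
ref_proteins <- function(family = NULL) {
  seqs <- cache_get("ref_proteins", function() {
    fa <- Biostrings::readAAStringSet(
      mercmags_extdata("synthetic_reference_proteins.faa"))
    setNames(as.character(fa), sub(" .*", "", names(fa)))
  })
  if (is.null(family)) return(seqs)
  id <- paste0(family, "_ref")
  if (!id %in% names(seqs)) {
    abort(paste0("no packaged reference for family: ", family))
  }
  seqs[id]
}

#' Packaged seed alignment for a family profile
#'
#' Each family ships a small aligned FASTA (the synthetic reference plus
#' three 5%-diverged variants with signature residues preserved) from which
#' the default scoring profiles are built.
#'
#' @param family One of `"hgcA"`, `"hgcB"`, `"merA"`, `"merB"`, `"rpoB"`.
#' @return Named character vector of equal-length aligned sequences.
#' @export
ref_seed_alignment <- function(family) {
  path <- system.file("extdata", sprintf("seed_%s_synthetic.afa", family),
                      package = "mercmags")
  if (!nzchar(path)) abort(paste0("no packaged seed alignment for: ", family))
  fa <- Biostrings::readAAStringSet(path)
  setNames(as.character(fa), names(fa))
}

#' Read a residue-signature specification table
#'
#' A signature spec lists, per family, the 1-based positions on the ungapped
#' reference protein and the amino acids allowed there. The packaged default
#' encodes the MerB C96/D99/C117/C159 signature and the MerA essential
#' cysteine pairs on the synthetic references; users can point this at their
#' own TSV to change positions or references.
#'
#' @param path Path to a TSV with columns `family`, `reference_id`,
#'   `position`, `allowed_residues` (string of one-letter codes). Defaults
#'   to the packaged spec.
#' @return A tibble, positions sorted within family.
#' @export
#' @examples
#' read_signature_spec()
read_signature_spec <- function(path = NULL) {
  if (is.null(path)) {
    return(cache_get("signature_spec", function()
      read_signature_spec(mercmags_extdata("signature_spec.tsv"))))
  }
  spec <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            family = "c", reference_id = "c",
                            position = "i", allowed_residues = "c"))
  need <- c("family", "reference_id", "position", "allowed_residues")
  if (!all(need %in% names(spec))) {
    abort("signature spec must have columns family, reference_id, position, allowed_residues")
  }
  if (any(spec$position < 1)) abort("signature positions must be >= 1")
  arrange(as_tibble(spec), .data$family, .data$position)
}

#' Summary table of mercury-gene MAGs from two brackish microbial mats
#'
#' A curated per-MAG summary for the 23 mercury-cycling-gene-bearing
#' metagenome-assembled genomes recovered from two Mediterranean brackish
#' lagoon microbial mats (an oil-refinery-impacted lagoon, EDB, and a nearby
#' bird-reserve lagoon, SL): taxonomy, CheckM-style completeness and
#' contamination, average read coverage (a relative-abundance proxy),
#' mercury gene content, and per-bin gene and expressed-gene counts. Used as
#' the worked example for the summary statistics in this package.
#'
#' @return A tibble with one row per MAG.
#' @export
#' @examples
#' mat_mag_summary() |> column_mean_sd("n_genes_expressed")
mat_mag_summary <- function() {
  tb <- readr::read_tsv(mercmags_extdata("mat_mag_summary.tsv"),
                        show_col_types = FALSE)
  as_tibble(tb) |>
    rename(completeness = "completeness_pct",
           contamination = "contamination_pct")
}

#' Genome-database co-occurrence counts for merB and merA
#'
#' Counts from mining a large public genome database for the organomercury
#' lyase gene: of 4530 genomes carrying `merB`, 1545 also carry the mercuric
#' reductase `merA`. The percentage is the package's worked example for
#' reporting rounded co-occurrence rates.
#'
#' @return A one-row tibble with `n_merB_genomes`, `n_with_merA`, and
#'   `pct_with_merA` (half-up rounded percent).
#' @export
#' @examples
#' mer_cooccurrence_counts()$pct_with_merA
mer_cooccurrence_counts <- function() {
  tibble(n_merB_genomes = 4530L, n_with_merA = 1545L,
         pct_with_merA = round_half_up(100 * 1545 / 4530))
}
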