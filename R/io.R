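#' Write a synthetic community to disk as standard flat files
#'
#' Writes the community the way a binning/annotation pipeline would hand
#' it over: contig nucleotide FASTA, protein FASTA (protein ids equal the
#' GFF3 gene ids), a GFF3 gene-coordinate table (1-based inclusive,
#' strand in column 7, `ID` attribute), a MAG quality TSV, a per-contig
#' per-sample DNA coverage TSV and the planted ground-truth TSV. Output
#' is deterministic: the same community writes byte-identical files.
#'
#' @param community A [generate_community()] result.
#' @param dir Output directory (created if needed).
#' @return The community, invisibly, with `dir` set.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synth_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  dna <- Biostrings::DNAStringSet(setNames(community$contigs$sequence,
                                           community$contigs$contig_id))
  Biostrings::writeXStringSet(dna, file.path(dir, "contigs.fna"))
  aa <- Biostrings::AAStringSet(setNames(community$genes$protein,
                                         community$genes$gene_id))
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.faa"))

  gff <- community$genes |>
    mutate(source = "mercmags", type = "CDS", score = ".", phase = "0",
           attributes = paste0("ID=", .data$gene_id, ";mag_id=",
                               .data$mag_id)) |>
    select("contig_id", "source", "type", "start", "end", "score",
           "strand", "phase", "attributes")
  gff_path <- file.path(dir, "genes.gff3")
  writeLines("##gff-version 3", gff_path)
  readr::write_tsv(gff, gff_path, col_names = FALSE, append = TRUE)

  community$mag_quality |>
    rename(completeness_pct = "completeness",
           contamination_pct = "contamination") |>
    readr::write_tsv(file.path(dir, "mag_quality.tsv"))
  readr::write_tsv(community$dna_coverage, file.path(dir, "dna_coverage.tsv"))
  readr::write_tsv(community$truth, file.path(dir, "ground_truth.tsv"))

  community$dir <- dir
  invisible(community)
}

#' Read a community back from the flat files written by [write_community()]
#'
#' Rebuilds a `synth_community` object from disk. The GFF3 is parsed with
#' rtracklayer; planted-family labels are recovered from the ground-truth
#' TSV (genes not listed there are labeled `background`). A configuration
#' must be supplied (or defaults are used) because flat files do not carry
#' generator settings.
#'
#' @param dir Directory holding the community files.
#' @param config Optional [synth_config()] to attach.
#' @return A `synth_community` object.
#' @export
read_community <- function(dir, config = synth_config()) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_community requires the rtracklayer package")
  }
  need <- c("contigs.fna", "proteins.faa", "genes.gff3",
            "mag_quality.tsv", "dna_coverage.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(paste0("missing community files in ", dir, ": ",
                 paste(missing, collapse = ", ")))
  }

  dna <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fna"))
  aa <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"))
  quality <- readr::read_tsv(file.path(dir, "mag_quality.tsv"),
                             show_col_types = FALSE) |>
    rename(completeness = "completeness_pct",
           contamination = "contamination_pct")
  coverage <- readr::read_tsv(file.path(dir, "dna_coverage.tsv"),
                              show_col_types = FALSE)
  truth_path <- file.path(dir, "ground_truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    tibble(gene_id = character(), family = character(),
           signature_status = character(), operon_partner = character(),
           mag_id = character())
  }

  genes <- tibble(
    gene_id = gff$ID,
    mag_id = gff$mag_id,
    contig_id = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    protein = as.character(aa[gff$ID]))
  fam <- setNames(truth$family, truth$gene_id)
  role <- ifelse(genes$gene_id %in% truth$gene_id,
                 fam[genes$gene_id], "background")
  # operon truth rows label the hgcA member; partners are hgcB
  partner <- setNames(truth$operon_partner, truth$gene_id)
  role[role == "hgcAB_operon"] <- "hgcA"
  role[genes$gene_id %in% stats::na.omit(truth$operon_partner)] <- "hgcB"
  role[role == "merA_like"] <- "merA"
  role[role == "decoy_pndr_dld"] <- "decoy"
  genes$family <- role
  genes$signature_status <- ifelse(
    genes$gene_id %in% truth$gene_id,
    setNames(truth$signature_status, truth$gene_id)[genes$gene_id],
    NA_character_)
  genes$operon_partner <- ifelse(
    genes$gene_id %in% truth$gene_id,
    partner[genes$gene_id], NA_character_)

  contigs <- tibble(contig_id = names(dna),
                    mag_id = sub("_c\\d+$", "", names(dna)),
                    length = Biostrings::width(dna),
                    sequence = as.character(dna))

  structure(
    list(genes = genes, contigs = contigs, mag_quality = quality,
         dna_coverage = coverage, truth = as_tibble(truth),
         config = config, dir = dir),
    class = "synth_community")
}
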