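#' Find the hgcB gene downstream of an hgcA gene on its contig
#'
#' Mercury-methylation capability requires the hgcA corrinoid protein gene
#' to be followed on its contig by the hgcB ferredoxin gene. "Downstream"
#' is 3' of hgcA on hgcA's own strand: higher coordinates on `+`, lower on
#' `-`. The nearest downstream gene is examined; the context is reported
#' found only when that gene is an hgcB (by screening hit or annotation
#' label), lies on the same strand, and starts within `max_intergenic`
#' bases of the hgcA end. Any intervening non-hgcB gene, an
#' opposite-strand hgcB, or a larger gap all yield an absent context.
#'
#' @param hgcA_gene_id Gene id of the hgcA candidate.
#' @param contig_genes Tibble of the genes on one contig: columns
#'   `gene_id`, `start`, `end`, `strand` (`"+"`/`"-"`), 1-based inclusive
#'   coordinates.
#' @param hgcB_ids Character vector of gene ids identified as hgcB.
#' @param max_intergenic Maximum intergenic distance in bp (default 200).
#' @return A one-row tibble: `hgcA_gene_id`, `hgcB_gene_id` (`NA` when
#'   absent), `intergenic_distance` (bp, `NA` when absent), `same_strand`,
#'   `found`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = c("a", "b"),
#'                         start = c(1000, 2050), end = c(1996, 2300),
#'                         strand = c("+", "+"))
#' find_hgcB_downstream("a", genes, hgcB_ids = "b")
find_hgcB_downstream <- function(hgcA_gene_id, contig_genes, hgcB_ids,
                                 max_intergenic = 200) {
  stopifnot(is.data.frame(contig_genes),
            all(c("gene_id", "start", "end", "strand") %in%
                  names(contig_genes)))
  if (!hgcA_gene_id %in% contig_genes$gene_id) {
    abort(paste0("hgcA gene not on the supplied contig: ", hgcA_gene_id))
  }
  a <- contig_genes[contig_genes$gene_id == hgcA_gene_id, ][1, ]
  others <- contig_genes[contig_genes$gene_id != hgcA_gene_id, ]

  absent <- tibble(hgcA_gene_id = hgcA_gene_id,
                   hgcB_gene_id = NA_character_,
                   intergenic_distance = NA_integer_,
                   same_strand = NA, found = FALSE)
  if (nrow(others) == 0) return(absent)

  if (a$strand == "+") {
    down <- others[others$start > a$end, ]
    if (nrow(down) == 0) return(absent)
    nearest <- down[which.min(down$start), ]
    dist <- nearest$start - a$end - 1L
  } else {
    down <- others[others$end < a$start, ]
    if (nrow(down) == 0) return(absent)
    nearest <- down[which.max(down$end), ]
    dist <- a$start - nearest$end - 1L
  }
  dist <- max(as.integer(dist), 0L)
  same_strand <- nearest$strand == a$strand
  is_hgcB <- nearest$gene_id %in% hgcB_ids
  if (is_hgcB && same_strand && dist <= max_intergenic) {
    tibble(hgcA_gene_id = hgcA_gene_id,
           hgcB_gene_id = nearest$gene_id,
           intergenic_distance = dist,
           same_strand = TRUE, found = TRUE)
  } else {
    absent
  }
}

#' Operon contexts for a set of hgcA candidates
#'
#' Applies [find_hgcB_downstream()] to every hgcA candidate, looking up
#' each candidate's contig from the gene table.
#'
#' @param hgcA_ids Character vector of hgcA candidate gene ids.
#' @param genes Gene table with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`.
#' @param hgcB_ids Gene ids identified as hgcB.
#' @param max_intergenic Maximum intergenic distance in bp.
#' @return A tibble with one row per hgcA candidate.
#' @export
operon_contexts <- function(hgcA_ids, genes, hgcB_ids, max_intergenic = 200) {
  stopifnot(all(c("gene_id", "contig_id", "start", "end", "strand") %in%
                  names(genes)))
  rows <- lapply(hgcA_ids, function(id) {
    ctg <- genes$contig_id[genes$gene_id == id]
    if (length(ctg) == 0) {
      abort(paste0("hgcA candidate not in gene table: ", id))
    }
    contig_genes <- genes[genes$contig_id == ctg[1], ]
    find_hgcB_downstream(id, contig_genes, hgcB_ids, max_intergenic)
  })
  list_rbind(rows)
}
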