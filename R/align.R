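#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix as shipped with Biostrings, used as the
#' default for [global_align()].
#'
#' @return An integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment of a query against a reference.
#' A gap run of length L costs `gap_open + gap_extend * L`. The traceback is
#' deterministic with fixed tie order: diagonal, then gap in query, then gap
#' in reference, so repeated calls always return the same alignment. An
#' empty query (or reference) yields the all-gap alignment with its forced
#' affine score.
#'
#' @param query,reference Protein strings (query may be empty).
#' @param substitution_matrix Scoring matrix with residue dimnames
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Non-negative gap penalties (defaults 11 and 1,
#'   the common protein-search convention).
#' @return An object of class `pairwise_alignment`: list with
#'   `aligned_query`, `aligned_reference` (equal-length gapped strings),
#'   `score`.
#' @export
#' @examples
#' global_align("ACDE", "ACDE")$score  # 4 + 9 + 6 + 5 = 24
global_align <- function(query, reference,
                         substitution_matrix = blosum62(),
                         gap_open = 11, gap_extend = 1) {
  stopifnot(is.character(query), length(query) == 1,
            is.character(reference), length(reference) == 1)
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be >= 0")
  qc <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  rc <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  resnames <- rownames(substitution_matrix)
  qi <- match(qc, resnames)
  ri <- match(rc, resnames)
  if (anyNA(qi)) {
    abort(paste0("residue not in substitution matrix: ",
                 paste(unique(qc[is.na(qi)]), collapse = ", ")))
  }
  if (anyNA(ri)) {
    abort(paste0("residue not in substitution matrix: ",
                 paste(unique(rc[is.na(ri)]), collapse = ", ")))
  }
  res <- nw_affine_cpp(qi, ri, substitution_matrix,
                       gap_open, gap_extend)
  aq <- ifelse(res$query_idx == 0, "-", qc[pmax(res$query_idx, 1)])
  ar <- ifelse(res$ref_idx == 0, "-", rc[pmax(res$ref_idx, 1)])
  structure(
    list(aligned_query = paste(aq, collapse = ""),
         aligned_reference = paste(ar, collapse = ""),
         score = res$score),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score = %g\n", x$score))
  cat("Q: ", x$aligned_query, "\n", sep = "")
  cat("R: ", x$aligned_reference, "\n", sep = "")
  invisible(x)
}

# Fraction of residue-residue columns that are identical; NA if the
# alignment has no residue-residue column.
alignment_identity <- function(alignment) {
  q <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  r <- strsplit(alignment$aligned_reference, "", fixed = TRUE)[[1]]
  both <- q != "-" & r != "-"
  if (!any(both)) return(NA_real_)
  mean(q[both] == r[both])
}

#' Map reference residue positions through a pairwise alignment
#'
#' Residue signatures are numbered on the ungapped reference protein; this
#' transfers each reference position to the 1-based query coordinate aligned
#' to it, or marks it deleted when the aligned column is a gap in the query.
#'
#' @param alignment A [global_align()] result (query vs reference).
#' @param positions Integer vector of 1-based positions on the ungapped
#'   reference.
#' @return A tibble: `reference_position`, `query_position` (`NA` when
#'   deleted), `deleted`, `query_residue` (`NA` when deleted), and
#'   `alignment_column` (the gapped-alignment column index).
#' @export
#' @examples
#' aln <- global_align("ACDE", "ACDE")
#' map_reference_positions(aln, c(1, 4))
map_reference_positions <- function(alignment, positions) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  q <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  r <- strsplit(alignment$aligned_reference, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(r != "-")
  ref_len <- max(ref_pos, 0L)
  if (any(positions < 1) || any(positions > ref_len)) {
    abort(sprintf("signature position beyond reference length (%d)", ref_len))
  }
  qry_pos <- cumsum(q != "-")
  cols <- match(positions, ifelse(r != "-", ref_pos, NA_integer_))
  deleted <- q[cols] == "-"
  tibble(reference_position = as.integer(positions),
         query_position = ifelse(deleted, NA_integer_,
                                 as.integer(qry_pos[cols])),
         deleted = deleted,
         query_residue = ifelse(deleted, NA_character_, q[cols]),
         alignment_column = as.integer(cols))
}

# Column indices (on the alignment) of the terminal query-gap runs, i.e.
# the leading and trailing stretches where the query is absent. Signature
# positions falling there indicate a truncated gene, not an ablated one.
terminal_gap_columns <- function(alignment) {
  q <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  non_gap <- which(q != "-")
  if (length(non_gap) == 0) return(seq_along(q))
  c(seq_len(non_gap[1] - 1L),
    if (non_gap[length(non_gap)] < length(q))
      (non_gap[length(non_gap)] + 1L):length(q))
}
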