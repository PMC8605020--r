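#' Check a residue signature on a candidate protein
#'
#' Aligns the candidate globally to the family reference ([global_align()]),
#' transfers the signature positions through the alignment
#' ([map_reference_positions()]), and passes the candidate iff every
#' required position carries an allowed residue. Three safeguards mirror
#' how curators treat edge cases:
#'
#' * a signature position falling in a terminal unaligned region (the gene
#'   is truncated across it) makes the result `indeterminate`, never
#'   `"<family>_like"` — an incomplete gene cannot be called
#'   signature-less;
#' * a candidate whose overall alignment identity to the reference falls
#'   below `min_identity` is `indeterminate` with reason
#'   `divergent_homolog`: such sequences (e.g. pyridine-nucleotide
#'   disulfide oxidoreductase relatives of MerA, the classic pndr/dld
#'   misannotations) are not family members at all and must not be
#'   reported as signature-lacking variants;
#' * an internal deletion at a required position counts as a failed
#'   position (`found = "-"`).
#'
#' @param protein Candidate protein string.
#' @param spec Signature rows for one family, as from
#'   [read_signature_spec()] (columns `family`, `position`,
#'   `allowed_residues`).
#' @param reference Reference protein the positions are numbered on
#'   (default: the packaged reference for `spec$family`).
#' @param min_identity Identity floor in `[0, 1]` below which the candidate
#'   is classified `indeterminate` (`NULL` disables the floor).
#' @param substitution_matrix,gap_open,gap_extend Passed to
#'   [global_align()].
#' @return An object of class `signature_result`: list with `family`,
#'   `pass`, `classification` (`"<family>"`, `"<family>_like"` or
#'   `"indeterminate"`), `reason` (`"signature"`, `"truncated"` or
#'   `"divergent_homolog"`), `identity`, and `positions` (a tibble with
#'   `reference_position`, `required`, `found`, `ok`).
#' @export
#' @examples
#' spec <- read_signature_spec() |> dplyr::filter(family == "merB")
#' check_signature(ref_proteins("merB"), spec)$classification
check_signature <- function(protein, spec, reference = NULL,
                            min_identity = NULL,
                            substitution_matrix = blosum62(),
                            gap_open = 11, gap_extend = 1) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1)
  family <- unique(spec$family)
  if (length(family) != 1) abort("spec must describe a single family")
  reference <- reference %||% unname(ref_proteins(family))

  aln <- global_align(protein, reference,
                      substitution_matrix = substitution_matrix,
                      gap_open = gap_open, gap_extend = gap_extend)
  mapped <- map_reference_positions(aln, spec$position)
  allowed <- strsplit(toupper(spec$allowed_residues), "", fixed = TRUE)
  found <- ifelse(mapped$deleted, "-", mapped$query_residue)
  ok <- mapped$deleted == FALSE &
    map2(mapped$query_residue, allowed, function(res, all) res %in% all) |>
    unlist()

  term_cols <- terminal_gap_columns(aln)
  truncated <- any(mapped$alignment_column %in% term_cols)
  identity <- alignment_identity(aln)
  divergent <- !is.null(min_identity) &&
    (is.na(identity) || identity < min_identity)

  pass <- all(ok) && !truncated && !divergent
  if (divergent) {
    classification <- "indeterminate"; reason <- "divergent_homolog"
  } else if (truncated) {
    classification <- "indeterminate"; reason <- "truncated"
  } else if (pass) {
    classification <- family; reason <- "signature"
  } else {
    classification <- paste0(family, "_like"); reason <- "signature"
  }

  structure(
    list(family = family, pass = pass, classification = classification,
         reason = reason, identity = identity,
         positions = tibble(
           reference_position = mapped$reference_position,
           required = spec$allowed_residues,
           found = found, ok = ok),
         alignment = aln),
    class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %s: %s (pass = %s, identity = %s)\n",
              x$family, x$classification, x$pass,
              ifelse(is.na(x$identity), "NA",
                     sprintf("%.1f%%", 100 * x$identity))))
  print(x$positions)
  invisible(x)
}

#' Classify a merA screening candidate as merA, merA-like or indeterminate
#'
#' Implements the curation rule for mercuric-reductase candidates: a
#' complete sequence carrying the essential cysteine pairs is `merA`; a
#' complete close homolog lacking them is `merA_like`; a sequence truncated
#' across any signature position, or one too divergent from the reference
#' to be a family member (below `min_identity`), is `indeterminate`.
#'
#' @param protein Candidate protein (should already have passed merA
#'   screening).
#' @param spec merA signature rows (default: packaged spec).
#' @param reference merA reference protein (default: packaged).
#' @param min_identity Identity floor separating true merA/merA-like
#'   homologs from divergent disulfide-oxidoreductase relatives
#'   (default 0.8).
#' @param ... Passed to [check_signature()].
#' @return A `signature_result` whose `classification` is one of `"merA"`,
#'   `"merA_like"`, `"indeterminate"`.
#' @export
#' @examples
#' classify_merA(ref_proteins("merA"))$classification
classify_merA <- function(protein, spec = NULL, reference = NULL,
                          min_identity = 0.8, ...) {
  spec <- spec %||% filter(read_signature_spec(), .data$family == "merA")
  check_signature(protein, spec, reference = reference,
                  min_identity = min_identity, ...)
}
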