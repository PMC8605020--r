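#' Build a position-specific log-odds scoring profile from a seed alignment
#'
#' Columns of the alignment become profile positions. Columns that are gaps
#' in at least half of the rows are dropped. Per-column residue frequencies
#' are mixed with the background by a Laplace-style pseudocount:
#' `f = (count + w * bg) / (n_col + w)` where `n_col` is the number of
#' non-gap rows in the column, and scored as `log2(f / bg)` bits. With the
#' default uniform background a perfectly conserved residue approaches
#' `log2(20) ~ 4.32` bits as `w -> 0`.
#'
#' @param seed_alignment Named character vector of equal-length aligned
#'   sequences (gaps as `-` or `.`), or a path to an aligned FASTA.
#' @param family Family label stored on the profile (defaults to the name of
#'   the first sequence, trimmed of `_ref`/`_seed` suffixes).
#' @param pseudocount_weight Positive pseudocount weight `w` (default 1).
#' @param background Residue background frequencies over [aa_alphabet()];
#'   default uniform. Must sum to 1.
#' @return An object of class `pssm_profile`: list with `family`, `length`,
#'   `log_odds` (20 x length bit-score matrix), `background`, `built_from`.
#' @export
#' @examples
#' p <- build_profile(c(a = "AC", b = "AD"), family = "toy")
#' p$length
build_profile <- function(seed_alignment, family = NULL,
                          pseudocount_weight = 1, background = NULL) {
  if (is.character(seed_alignment) && length(seed_alignment) == 1 &&
      file.exists(seed_alignment)) {
    fa <- Biostrings::readAAStringSet(seed_alignment)
    seed_alignment <- setNames(as.character(fa), names(fa))
  }
  if (length(seed_alignment) == 0) abort("seed alignment is empty")
  if (pseudocount_weight <= 0) abort("pseudocount_weight must be > 0")
  widths <- nchar(seed_alignment)
  if (length(unique(widths)) != 1) {
    abort("ragged seed alignment: rows must have equal length")
  }
  if (widths[1] == 0) abort("seed alignment has zero columns")

  alpha <- aa_alphabet()
  bg <- background %||% rep(1 / 20, 20)
  if (length(bg) != 20 || abs(sum(bg) - 1) > 1e-9 || any(bg <= 0)) {
    abort("background must be 20 positive frequencies summing to 1")
  }
  names(bg) <- alpha

  chars <- do.call(rbind, strsplit(toupper(seed_alignment), "", fixed = TRUE))
  chars[chars == "."] <- "-"
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac < 0.5)
  if (length(keep) == 0) abort("all alignment columns are majority-gap")

  log_odds <- vapply(keep, function(j) {
    col <- chars[, j]
    col <- col[col != "-"]
    counts <- table(factor(col, levels = alpha))
    f <- (as.numeric(counts) + pseudocount_weight * bg) /
      (length(col) + pseudocount_weight)
    as.numeric(log2(f / bg))
  }, numeric(20))
  log_odds <- matrix(log_odds, nrow = 20,
                     dimnames = list(alpha, NULL))

  fam <- family %||% sub("(_ref|_seed.*)$", "", names(seed_alignment)[1])
  structure(
    list(family = fam %||% "profile", length = length(keep),
         log_odds = log_odds, background = bg,
         built_from = paste(names(seed_alignment), collapse = ",")),
    class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> family=%s, %d columns, built from: %s\n",
              x$family, x$length, x$built_from))
  invisible(x)
}

#' Score a protein against a profile over all ungapped placements
#'
#' The bit score is the maximum, over all ungapped placements of the profile
#' along the protein, of the summed per-column log-odds scores; ties break
#' toward the smallest start. Residues outside the 20-letter alphabet score
#' 0 bits. Proteins shorter than the profile admit no placement and return
#' `NA` scores.
#'
#' @param profile A [build_profile()] object.
#' @param protein A single protein string.
#' @return A one-row tibble: `bit_score`, `span_start`, `span_end` (1-based
#'   inclusive on the protein), `n_placements`.
#' @export
score_protein <- function(profile, protein) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (!is.character(protein) || length(protein) != 1 || !nzchar(protein)) {
    abort("protein must be a single non-empty string")
  }
  hit <- pssm_scan_cpp(encode_protein(protein), profile$log_odds)
  tibble(bit_score = hit$score,
         span_start = hit$start,
         span_end = if (is.na(hit$start)) NA_integer_ else
           hit$start + profile$length - 1L,
         n_placements = hit$n_placements)
}

#' E-value for a profile bit score
#'
#' `E = n_targets * max(mean_target_length - profile_length + 1, 1) *
#' 2^(-bit_score)`: the expected number of equal-or-better ungapped
#' placements in a search of the given size under the base-2 bit-score
#' convention. High bit scores underflow double precision, so comparisons
#' against thresholds should use `log10 = TRUE`.
#'
#' @param bit_score Numeric vector of bit scores.
#' @param n_targets Number of target sequences searched.
#' @param profile_length Profile columns.
#' @param mean_target_length Mean target sequence length; the per-target
#'   placement count is floored at 1.
#' @param log10 If `TRUE`, return `log10(E)` instead of `E`.
#' @return Numeric vector of e-values (or their log10).
#' @export
#' @examples
#' profile_evalue(10, n_targets = 100, profile_length = 20,
#'                mean_target_length = 300)
profile_evalue <- function(bit_score, n_targets, profile_length,
                           mean_target_length, log10 = FALSE) {
  if (n_targets <= 0 || profile_length <= 0 || mean_target_length <= 0) {
    abort("search-space sizes must be positive")
  }
  placements <- max(mean_target_length - profile_length + 1, 1)
  lg <- log10(n_targets * placements) - bit_score * log10(2)
  if (log10) lg else 10^lg
}

#' Default per-family e-value thresholds
#'
#' `merB` uses the fixed stringent threshold `exp(-120)` (~7.7e-53), the
#' filter applied to homology hits for that family; the remaining families
#' default to a conventional 1e-10 and are freely configurable.
#'
#' @param ... Named overrides, e.g. `merA = 1e-30`.
#' @return Named numeric vector of maximum e-values.
#' @export
#' @examples
#' default_family_thresholds(hgcA = 1e-20)
default_family_thresholds <- function(...) {
  th <- c(hgcA = 1e-10, hgcB = 1e-10, merA = 1e-10,
          merB = exp(-120), rpoB = 1e-10)
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      abort("threshold overrides must be named")
    }
    th[names(over)] <- over
  }
  if (any(th <= 0)) abort("thresholds must be strictly positive")
  th
}

#' Build the packaged default profiles for all screened families
#'
#' @param families Families to build (default all five).
#' @param pseudocount_weight Passed to [build_profile()].
#' @return Named list of `pssm_profile` objects.
#' @export
family_profiles <- function(families = c("hgcA", "hgcB", "merA", "merB", "rpoB"),
                            pseudocount_weight = 1) {
  setNames(lapply(families, function(f) {
    build_profile(ref_seed_alignment(f), family = f,
                  pseudocount_weight = pseudocount_weight)
  }), families)
}

#' Screen proteins against family profiles with e-value thresholds
#'
#' Every protein is scored against every profile; hits at or below the
#' family's e-value threshold are retained. A protein may hit several
#' families — downstream validation disambiguates. Threshold comparison is
#' done in log10 space so that extremely strong hits (whose e-values
#' underflow to 0) are handled exactly.
#'
#' @param proteins A tibble with columns `gene_id` and `protein`, or a named
#'   character vector of protein sequences.
#' @param profiles Named list of [build_profile()] objects (default: the
#'   packaged [family_profiles()]).
#' @param thresholds Named numeric vector of per-family maximum e-values
#'   ([default_family_thresholds()]). Every profile family must have one.
#' @return A tibble sorted by (family, e-value, gene_id): `gene_id`,
#'   `family`, `bit_score`, `e_value`, `log10_evalue`, `span_start`,
#'   `span_end`.
#' @export
#' @examples
#' prots <- c(g1 = ref_proteins("merB"))
#' screen_families(prots, family_profiles("merB"))
screen_families <- function(proteins, profiles = family_profiles(),
                            thresholds = default_family_thresholds()) {
  if (is.character(proteins)) {
    proteins <- tibble(gene_id = names(proteins) %||%
                         paste0("g", seq_along(proteins)),
                       protein = unname(proteins))
  }
  stopifnot(all(c("gene_id", "protein") %in% names(proteins)))
  missing_th <- setdiff(names(profiles), names(thresholds))
  if (length(missing_th)) {
    abort(paste0("no e-value threshold configured for family: ",
                 paste(missing_th, collapse = ", ")))
  }
  empty <- tibble(gene_id = character(), family = character(),
                  bit_score = double(), e_value = double(),
                  log10_evalue = double(),
                  span_start = integer(), span_end = integer())
  if (nrow(proteins) == 0) return(empty)

  n_targets <- nrow(proteins)
  mean_len <- mean(nchar(proteins$protein))
  encoded <- lapply(proteins$protein, encode_protein)

  hits <- lapply(names(profiles), function(fam) {
    prof <- profiles[[fam]]
    rows <- lapply(seq_len(n_targets), function(i) {
      h <- pssm_scan_cpp(encoded[[i]], prof$log_odds)
      if (is.na(h$score)) return(NULL)
      lg <- profile_evalue(h$score, n_targets, prof$length, mean_len,
                           log10 = TRUE)
      if (lg > log10(thresholds[[fam]])) return(NULL)
      tibble(gene_id = proteins$gene_id[i], family = fam,
             bit_score = h$score, e_value = 10^lg, log10_evalue = lg,
             span_start = h$start,
             span_end = h$start + prof$length - 1L)
    })
    list_rbind(rows[!vapply(rows, is.null, logical(1))])
  })
  out <- list_rbind(hits)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$family, .data$log10_evalue, .data$gene_id)
}
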