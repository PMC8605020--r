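# Shared fixtures, built in code and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, compute) {
  if (!exists(key, envir = .fixtures)) assign(key, compute(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small noiseless community: 5 hgcAB operons, 3 merA, 2 merA-like,
# 2 merB, a handful of decoys, across 8 MAGs.
noiseless_config <- function(seed = 101, decoys = 6L) {
  synth_config(
    n_mags = 8, contigs_per_mag = c(2, 3), mean_genes_per_contig = 5,
    planted = tibble::tibble(
      family = c("hgcAB_operon", "merA", "merA_like", "merB",
                 "decoy_pndr_dld"),
      n = c(5L, 3L, 2L, 2L, decoys)),
    mutation_rate = 0, seed = seed)
}

noiseless_run <- function() {
  fixture("noiseless_run", function() run_pipeline(noiseless_config()))
}

# Brute-force placement maximum for an ungapped profile scan (R-side
# oracle, independent of the C++ scan).
brute_pssm_score <- function(profile, protein) {
  idx <- match(strsplit(protein, "")[[1]], aa_alphabet())
  L <- profile$length
  n <- length(idx)
  if (n < L) return(NA_real_)
  scores <- vapply(seq_len(n - L + 1), function(s) {
    sum(vapply(seq_len(L), function(j) {
      a <- idx[s + j - 1]
      if (is.na(a)) 0 else profile$log_odds[a, j]
    }, numeric(1)))
  }, numeric(1))
  max(scores)
}

random_peptide <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
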