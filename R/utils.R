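#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Residues are ordered alphabetically by one-letter code. Profile matrices
#' index rows in this order; unknown letters (e.g. `X`) are scored as
#' background (0 bits).
#'
#' @return A character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Encode a protein string as 1-based indices into aa_alphabet(); 0 = unknown.
encode_protein <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  idx <- match(chars, aa_alphabet())
  idx[is.na(idx)] <- 0L
  idx
}

#' Round half away from zero
#'
#' Reported means and percentages are rounded half-up (2409.5 -> 2410),
#' unlike [round()]'s round-half-to-even. Full precision is always retained
#' internally; this is a reporting convention only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.5, 34.105, -2.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stage-specific 32-bit seed from the run seed so that independent
# stages (community layout, transcript draws, ...) consume independent
# streams while remaining fully determined by the single user-facing seed.
derive_seed <- function(seed, stage) {
  offsets <- c(community = 101L, transcripts = 211L, coverage = 307L)
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown RNG stage: ", stage))
  }
  as.integer((as.double(seed) * 48271 + offsets[[stage]]) %% 2147483647)
}

assert_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(paste0(what, " must be finite and non-negative"))
  }
  invisible(x)
}

# Session cache for packaged reference data (spec, FASTA reads).
.mercmags_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .mercmags_cache)) {
    assign(key, compute(), envir = .mercmags_cache)
  }
  get(key, envir = .mercmags_cache)
}

# Path to a file shipped under inst/extdata.
mercmags_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mercmags")
  if (!nzchar(path)) abort(paste0("packaged data file not found: ", file))
  path
}
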