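#' Quality-filter MAGs on completeness and contamination
#'
#' Retains exactly the MAGs with completeness strictly above 50% and
#' contamination strictly under 5% — the conventional medium-quality bar
#' for analyzing metagenome-assembled genomes. Order is preserved and the
#' filter is idempotent.
#'
#' @param mags Tibble with columns `mag_id`, `completeness`,
#'   `contamination` (percent).
#' @param min_completeness,max_contamination Strict bounds (defaults 50
#'   and 5).
#' @return The retained rows, same column order.
#' @export
#' @examples
#' quality_filter_mags(tibble::tibble(
#'   mag_id = c("a", "b"), completeness = c(57.45, 50),
#'   contamination = c(2.65, 1)))
quality_filter_mags <- function(mags, min_completeness = 50,
                                max_contamination = 5) {
  need <- c("mag_id", "completeness", "contamination")
  if (!is.data.frame(mags) || !all(need %in% names(mags))) {
    abort("mags must have columns mag_id, completeness, contamination")
  }
  if (anyNA(mags$completeness) || anyNA(mags$contamination)) {
    abort("completeness/contamination must not be missing")
  }
  filter(as_tibble(mags),
         .data$completeness > min_completeness,
         .data$contamination < max_contamination)
}

#' Length-weighted MAG coverage from per-contig depths
#'
#' MAG coverage (reads per base) is the length-weighted mean of its
#' contigs' mean depths, computed per sample when a `sample_id` column is
#' present.
#'
#' @param contig_depths Tibble with columns `mag_id`, `length`,
#'   `mean_depth`, and optionally `sample_id`.
#' @return A tibble with one row per MAG (x sample): `mag_id`,
#'   (`sample_id`,) `coverage`.
#' @export
#' @examples
#' mag_coverage(tibble::tibble(mag_id = "m", length = c(100, 300),
#'                             mean_depth = c(2, 4)))  # 3.5
mag_coverage <- function(contig_depths) {
  need <- c("mag_id", "length", "mean_depth")
  if (!is.data.frame(contig_depths) || nrow(contig_depths) == 0 ||
      !all(need %in% names(contig_depths))) {
    abort("contig_depths must be non-empty with mag_id, length, mean_depth")
  }
  if (any(contig_depths$length <= 0)) abort("contig lengths must be > 0")
  assert_nonneg(contig_depths$mean_depth, "mean_depth")
  keys <- intersect(c("mag_id", "sample_id"), names(contig_depths))
  contig_depths |>
    as_tibble() |>
    group_by(across(all_of(keys))) |>
    summarise(coverage = sum(.data$length * .data$mean_depth) /
                sum(.data$length), .groups = "drop")
}

#' Community abundance summary and above/below-average classes
#'
#' Coverage is used as a proxy for the relative abundance of each MAG's
#' population. The summary reports the community mean, median and maximum
#' coverage and classes each MAG as `above_average` (strictly greater
#' than the community mean) or `below_average`.
#'
#' @param mags Tibble with columns `mag_id`, `coverage` (one row per MAG).
#' @return A list of class `abundance_summary`: `stats` (one-row tibble
#'   with `mean`, `median`, `max`, `n`) and `mags` (per-MAG tibble with
#'   `abundance_class`).
#' @export
#' @examples
#' abundance_summary(tibble::tibble(mag_id = c("a", "b", "c"),
#'                                  coverage = c(1, 2, 3)))
abundance_summary <- function(mags) {
  if (!is.data.frame(mags) || nrow(mags) == 0 ||
      !all(c("mag_id", "coverage") %in% names(mags))) {
    abort("mags must be non-empty with columns mag_id, coverage")
  }
  assert_nonneg(mags$coverage, "coverage")
  mu <- mean(mags$coverage)
  stats <- tibble(mean = mu, median = median(mags$coverage),
                  max = max(mags$coverage), n = nrow(mags))
  per_mag <- mags |>
    as_tibble() |>
    mutate(abundance_class = ifelse(.data$coverage > mu,
                                    "above_average", "below_average"))
  structure(list(stats = stats, mags = per_mag),
            class = "abundance_summary")
}

#' @export
print.abundance_summary <- function(x, ...) {
  cat(sprintf(
    "<abundance_summary> n = %d, mean = %.3g, median = %.3g, max = %.3g\n",
    x$stats$n, x$stats$mean, x$stats$median, x$stats$max))
  cat(sprintf("  %d above average, %d below\n",
              sum(x$mags$abundance_class == "above_average"),
              sum(x$mags$abundance_class == "below_average")))
  invisible(x)
}

expression_categories <- c("not_expressed", "lower", "similar", "higher",
                           "undetermined")

#' Normalize gene transcript coverage to the rpoB housekeeping gene
#'
#' The expression level of a gene of interest is expressed as the ratio of
#' its transcript coverage to the coverage of the RNA polymerase subunit B
#' (rpoB) gene of the same bin, discriminating low from high expression
#' relative to a housekeeping baseline. Categories: `not_expressed` when
#' the gene coverage is 0; `lower`/`similar`/`higher` by comparing the
#' ratio to the `similar_band`; `undetermined` when rpoB coverage is 0 but
#' the gene is detected (no baseline - never an infinite ratio).
#'
#' @param gene_cov,rpoB_cov Nonnegative transcript coverages (vectorized).
#' @param similar_band `c(lo, hi)` with `0 < lo <= 1 <= hi`; ratios within
#'   the band (inclusive) are `similar`. Default `c(0.5, 2)`, a symmetric
#'   two-fold band.
#' @return A tibble: `ratio` (`NA` when undetermined) and `category`
#'   (factor with levels `r paste(expression_categories, collapse = ", ")`).
#' @export
#' @examples
#' normalize_to_rpoB(c(0, 5, 10), c(7, 5, 2))
normalize_to_rpoB <- function(gene_cov, rpoB_cov, similar_band = c(0.5, 2)) {
  assert_nonneg(gene_cov, "gene_cov")
  assert_nonneg(rpoB_cov, "rpoB_cov")
  if (length(similar_band) != 2 || similar_band[1] <= 0 ||
      similar_band[1] > 1 || similar_band[2] < 1) {
    abort("similar_band must be (lo, hi) with 0 < lo <= 1 <= hi")
  }
  n <- max(length(gene_cov), length(rpoB_cov))
  gene_cov <- rep_len(gene_cov, n)
  rpoB_cov <- rep_len(rpoB_cov, n)
  ratio <- ifelse(rpoB_cov > 0, gene_cov / rpoB_cov,
                  ifelse(gene_cov == 0, 0, NA_real_))
  category <- case_when(
    gene_cov == 0 ~ "not_expressed",
    rpoB_cov == 0 ~ "undetermined",
    ratio < similar_band[1] ~ "lower",
    ratio > similar_band[2] ~ "higher",
    .default = "similar")
  tibble(ratio = ratio,
         category = factor(category, levels = expression_categories))
}

#' Summed expression profile of one MAG across sampling periods
#'
#' For a whole-bin expression overview, transcripts of each gene are
#' summed over all sampling periods and the summed count is compared to
#' the summed rpoB transcript count of the same bin, with the same
#' similarity band as the per-sample ratios. Scaling all coverages in all
#' samples by a constant leaves every summed ratio unchanged.
#'
#' @param expression Long tibble for a single MAG with columns `mag_id`,
#'   `gene_id`, `sample_id`, `transcript_coverage`, `rpoB_coverage`.
#' @param gene_set Optional gene ids to restrict to.
#' @param similar_band Passed to [normalize_to_rpoB()].
#' @return A tibble with one row per gene: `mag_id`, `gene_id`,
#'   `summed_coverage`, `summed_rpoB`, `ratio`, `category`.
#' @export
summed_pathway_profile <- function(expression, gene_set = NULL,
                                   similar_band = c(0.5, 2)) {
  need <- c("mag_id", "gene_id", "sample_id", "transcript_coverage",
            "rpoB_coverage")
  if (!is.data.frame(expression) || !all(need %in% names(expression))) {
    abort(paste0("expression must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (length(unique(expression$mag_id)) > 1) {
    abort("summed_pathway_profile expects records from a single MAG")
  }
  if (!is.null(gene_set)) {
    expression <- filter(expression, .data$gene_id %in% gene_set)
  }
  sums <- expression |>
    as_tibble() |>
    group_by(.data$mag_id, .data$gene_id) |>
    summarise(summed_coverage = sum(.data$transcript_coverage),
              summed_rpoB = sum(.data$rpoB_coverage), .groups = "drop")
  norm <- normalize_to_rpoB(sums$summed_coverage, sums$summed_rpoB,
                            similar_band)
  bind_cols(sums, norm)
}

#' Mean and sample standard deviation of a numeric column
#'
#' The reporting helper behind "mean +/- sd" summaries such as the average
#' number of expressed genes per bin. The sample standard deviation uses
#' the n-1 denominator and is `NA` for a single value.
#'
#' @param data A data frame, or a bare numeric vector.
#' @param col Column name (tidy-selected) when `data` is a data frame.
#' @return A one-row tibble: `n`, `mean`, `sd`.
#' @export
#' @examples
#' column_mean_sd(c(1, 2, 3))
#' mat_mag_summary() |> column_mean_sd("n_genes_expressed")
column_mean_sd <- function(data, col = NULL) {
  values <- if (is.data.frame(data)) {
    if (is.null(col)) abort("col is required when data is a data frame")
    data[[if (is.character(col)) col else rlang::as_name(rlang::enquo(col))]]
  } else {
    data
  }
  if (length(values) == 0 || !is.numeric(values)) {
    abort("need at least one numeric value")
  }
  tibble(n = length(values), mean = mean(values),
         sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}

#' Bray-Curtis similarity between two count vectors, in percent
#'
#' `100 * 2 * sum(pmin(a, b)) / (sum(a) + sum(b))`: 100 for identical
#' composition, 0 for disjoint supports. Symmetric, bounded in `[0, 100]`.
#'
#' @param a,b Equal-length nonnegative count vectors, not both all-zero.
#' @return A single percentage.
#' @export
#' @examples
#' bray_curtis_similarity(c(2, 1, 0), c(1, 1, 1))  # 66.67
bray_curtis_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  assert_nonneg(a, "a")
  assert_nonneg(b, "b")
  tot <- sum(a) + sum(b)
  if (tot == 0) abort("both vectors are all-zero")
  100 * 2 * sum(pmin(a, b)) / tot
}
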