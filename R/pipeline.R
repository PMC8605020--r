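#' Run the full mercury-gene profiling pipeline
#'
#' Orchestrates the analysis end to end on a synthetic (or re-loaded)
#' community: MAG quality filtering, profile screening of all proteins,
#' curation of candidates (hgcB operon context for hgcA; essential-cysteine
#' signatures for merA with divergent-homolog and truncation safeguards;
#' the four-residue signature for merB), and quantification (MAG coverage
#' and abundance classes, rpoB-normalized per-sample expression, summed
#' whole-run profiles). Identical configuration and seed give identical
#' outputs.
#'
#' @param config A [synth_config()]; ignored when `community` is given.
#' @param community Optional pre-built [generate_community()] object or a
#'   directory path understood by [read_community()].
#' @param thresholds Per-family e-value thresholds
#'   ([default_family_thresholds()]).
#' @param signature_spec Residue signature table ([read_signature_spec()]).
#' @param max_intergenic Maximum hgcA-hgcB intergenic distance in bp.
#' @param similar_band Ratio band treated as "similar" expression.
#' @param min_identity Identity floor for signature-based classification.
#' @param excluded_samples Sample ids dropped from the transcript analysis
#'   (e.g. failed libraries); empty by default.
#' @param out_dir Optional directory: when given, the result tables are
#'   written as TSVs.
#' @return An object of class `mercmags_run`; see [tidy.mercmags_run()]
#'   and [glance.mercmags_run()].
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(synth_config(n_mags = 6, seed = 1))
#' glance(run)
#' }
run_pipeline <- function(config = synth_config(),
                         community = NULL,
                         thresholds = default_family_thresholds(),
                         signature_spec = read_signature_spec(),
                         max_intergenic = 200,
                         similar_band = c(0.5, 2),
                         min_identity = 0.8,
                         excluded_samples = character(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(community)) {
    community <- generate_community(config)
  } else if (is.character(community)) {
    community <- read_community(community, config = config)
  }
  stopifnot(inherits(community, "synth_community"))
  config <- community$config

  rna <- simulate_transcripts(community) |>
    filter(!.data$sample_id %in% excluded_samples)
  dna <- community$dna_coverage |>
    filter(!.data$sample_id %in% excluded_samples)

  # stage 1: MAG quality filter
  retained_mags <- quality_filter_mags(community$mag_quality)
  genes <- filter(community$genes, .data$mag_id %in% retained_mags$mag_id)

  # stage 2: profile screening
  profiles <- family_profiles()
  hits <- screen_families(genes[, c("gene_id", "protein")], profiles,
                          thresholds)
  hits <- left_join(hits, genes[, c("gene_id", "mag_id", "contig_id")],
                    by = "gene_id")

  # stage 3: curation
  prot_of <- setNames(genes$protein, genes$gene_id)
  hgcB_ids <- hits$gene_id[hits$family == "hgcB"]
  hgcA_ids <- hits$gene_id[hits$family == "hgcA"]
  operons <- if (length(hgcA_ids)) {
    operon_contexts(hgcA_ids, genes, hgcB_ids, max_intergenic)
  } else {
    tibble(hgcA_gene_id = character(), hgcB_gene_id = character(),
           intergenic_distance = integer(), same_strand = logical(),
           found = logical())
  }

  classify_family <- function(ids, fam) {
    spec <- filter(signature_spec, .data$family == fam)
    rows <- lapply(ids, function(id) {
      res <- check_signature(prot_of[[id]], spec,
                             min_identity = min_identity)
      tibble(gene_id = id, family = res$classification,
             signature_pass = res$pass, reason = res$reason,
             identity = res$identity)
    })
    list_rbind(rows)
  }
  merA_calls <- classify_family(hits$gene_id[hits$family == "merA"], "merA")
  merB_calls <- classify_family(hits$gene_id[hits$family == "merB"], "merB")

  validated <- bind_rows(
    operons |>
      filter(.data$found) |>
      transmute(gene_id = .data$hgcA_gene_id, family = "hgcAB",
                signature_pass = TRUE, reason = "operon_context",
                identity = NA_real_,
                operon_partner = .data$hgcB_gene_id,
                intergenic_distance = .data$intergenic_distance),
    bind_rows(merA_calls, merB_calls) |>
      filter(!.data$family %in% "indeterminate") |>
      mutate(operon_partner = NA_character_,
             intergenic_distance = NA_integer_))
  validated <- left_join(validated, genes[, c("gene_id", "mag_id")],
                         by = "gene_id") |>
    relocate("mag_id", .after = "gene_id")

  # rpoB genes anchor normalization; sum coverage over copies per MAG
  rpoB_genes <- hits |>
    filter(.data$family == "rpoB") |>
    select("gene_id", "mag_id")

  # stage 4: quantification
  contig_depths <- dna |>
    left_join(community$contigs[, c("contig_id", "length")],
              by = "contig_id")
  coverage_by_sample <- mag_coverage(contig_depths)
  mag_cov <- coverage_by_sample |>
    group_by(.data$mag_id) |>
    summarise(coverage = mean(.data$coverage), .groups = "drop") |>
    filter(.data$mag_id %in% retained_mags$mag_id)
  abundance <- if (nrow(mag_cov)) abundance_summary(mag_cov) else NULL

  rpoB_cov <- rna |>
    inner_join(rpoB_genes, by = "gene_id") |>
    group_by(.data$mag_id, .data$sample_id) |>
    summarise(rpoB_coverage = sum(.data$transcript_coverage),
              .groups = "drop")

  genes_of_interest <- bind_rows(
    validated[, c("gene_id", "mag_id", "family")],
    mutate(rpoB_genes, family = "rpoB"))
  expression <- genes_of_interest |>
    inner_join(rna, by = "gene_id") |>
    left_join(rpoB_cov, by = c("mag_id", "sample_id")) |>
    mutate(rpoB_coverage = coalesce(.data$rpoB_coverage, 0))
  expression <- bind_cols(
    expression,
    normalize_to_rpoB(expression$transcript_coverage,
                      expression$rpoB_coverage, similar_band))

  summed <- expression |>
    group_by(.data$mag_id) |>
    group_split() |>
    lapply(summed_pathway_profile, similar_band = similar_band) |>
    list_rbind()
  summed <- left_join(summed,
                      distinct(genes_of_interest[, c("gene_id", "family")]),
                      by = "gene_id") |>
    relocate("family", .after = "gene_id")

  n_candidates <- length(unique(
    hits$gene_id[hits$family %in% c("hgcA", "merA", "merB")]))
  report <- tibble(
    stage = c("mag_quality_filter", "screening", "curation"),
    n_in = c(nrow(community$mag_quality), nrow(genes), n_candidates),
    n_retained = c(nrow(retained_mags), length(unique(hits$gene_id)),
                   nrow(validated)))
  report$n_discarded <- report$n_in - report$n_retained

  run <- structure(
    list(community = community, config = config, hits = hits,
         operons = operons, validated = validated,
         rpoB_genes = rpoB_genes, expression = as_tibble(expression),
         summed = summed, abundance = abundance,
         coverage_by_sample = coverage_by_sample,
         report = report,
         params = list(thresholds = thresholds,
                       max_intergenic = max_intergenic,
                       similar_band = similar_band,
                       min_identity = min_identity,
                       excluded_samples = excluded_samples,
                       seed = config$seed),
         wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "mercmags_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write the result tables of a pipeline run as TSVs
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `run`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "mercmags_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(run$validated, file.path(dir, "validated_genes.tsv"))
  readr::write_tsv(run$expression, file.path(dir, "expression_profiles.tsv"))
  readr::write_tsv(run$summed, file.path(dir, "summed_profiles.tsv"))
  if (!is.null(run$abundance)) {
    readr::write_tsv(run$abundance$mags, file.path(dir, "mag_abundance.tsv"))
  }
  readr::write_tsv(run$report, file.path(dir, "run_report.tsv"))
  invisible(run)
}

#' @export
print.mercmags_run <- function(x, ...) {
  cat("<mercmags_run>\n")
  print(x$report)
  counts <- table(x$validated$family)
  if (length(counts)) {
    cat("validated calls: ",
        paste(sprintf("%s=%d", names(counts), as.integer(counts)),
              collapse = ", "), "\n", sep = "")
  } else {
    cat("validated calls: none\n")
  }
  invisible(x)
}

#' Tidy the validated mercury-gene calls of a run
#'
#' @param x A `mercmags_run`.
#' @param ... Unused.
#' @return The validated-calls tibble (one row per validated gene).
#' @export
tidy.mercmags_run <- function(x, ...) x$validated

#' One-row summary of a pipeline run
#'
#' @param x A `mercmags_run`.
#' @param ... Unused.
#' @return A one-row tibble of stage and per-family counts plus community
#'   coverage statistics.
#' @export
glance.mercmags_run <- function(x, ...) {
  fam_count <- function(f) sum(x$validated$family == f)
  tibble(
    n_mags = nrow(x$community$mag_quality),
    n_mags_retained = x$report$n_retained[1],
    n_genes = x$report$n_in[2],
    n_hits = x$report$n_retained[2],
    n_validated = nrow(x$validated),
    n_hgcAB = fam_count("hgcAB"),
    n_merA = fam_count("merA"),
    n_merA_like = fam_count("merA_like"),
    n_merB = fam_count("merB"),
    mean_coverage = if (is.null(x$abundance)) NA_real_
    else x$abundance$stats$mean,
    wall_time_s = x$wall_time_s)
}

#' Score validated calls against the planted ground truth
#'
#' Computes per-family precision and recall of the validated calls against
#' the generator's ground-truth labels, plus the merA vs merA-like
#' confusion table. Truth label `hgcAB_operon` corresponds to a validated
#' `hgcAB` call on the hgcA gene; decoy and rpoB plants are expected to
#' produce no validated mercury-gene call, so any call on them counts as
#' a false positive of the called family.
#'
#' @param outputs A `mercmags_run` or its validated-calls tibble
#'   (columns `gene_id`, `family`).
#' @param truth Ground-truth tibble (columns `gene_id`, `family`);
#'   defaults to the run's own.
#' @return A tibble with one row per family (`n_truth`, `n_predicted`,
#'   `tp`, `precision`, `recall`), with the merA/merA-like confusion
#'   table in attribute `"confusion"`.
#' @export
evaluate_against_truth <- function(outputs, truth = NULL) {
  if (inherits(outputs, "mercmags_run")) {
    truth <- truth %||% outputs$community$truth
    outputs <- outputs$validated
  }
  if (is.null(truth)) abort("truth table required")
  stopifnot(all(c("gene_id", "family") %in% names(outputs)),
            all(c("gene_id", "family") %in% names(truth)))
  if (anyDuplicated(truth$gene_id)) {
    abort("ground truth lists a gene_id more than once")
  }

  truth_fam <- truth |>
    mutate(family = recode(.data$family, hgcAB_operon = "hgcAB")) |>
    filter(.data$family %in% c("hgcAB", "merA", "merA_like", "merB"))
  pred <- distinct(as_tibble(outputs)[, c("gene_id", "family")])

  families <- sort(union(truth_fam$family, pred$family))
  rows <- lapply(families, function(f) {
    t_ids <- truth_fam$gene_id[truth_fam$family == f]
    p_ids <- pred$gene_id[pred$family == f]
    tp <- length(intersect(t_ids, p_ids))
    tibble(family = f, n_truth = length(t_ids),
           n_predicted = length(p_ids), tp = tp,
           precision = if (length(p_ids)) tp / length(p_ids) else NA_real_,
           recall = if (length(t_ids)) tp / length(t_ids) else NA_real_)
  })
  out <- list_rbind(rows)

  mer_truth <- truth_fam |> filter(.data$family %in% c("merA", "merA_like"))
  pred_of <- setNames(pred$family, pred$gene_id)
  confusion <- table(
    truth = mer_truth$family,
    predicted = factor(
      ifelse(mer_truth$gene_id %in% names(pred_of),
             pred_of[mer_truth$gene_id], "none"),
      levels = c("merA", "merA_like", "none")))
  attr(out, "confusion") <- confusion
  out
}
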