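planted_families <- c("hgcAB_operon", "merA", "merA_like", "merB",
                      "decoy_pndr_dld")

#' Default planted-gene design for the synthetic community
#'
#' Mirrors the mercury-gene census of the microbial-mat study the package
#' models: 10 hgcAB operons, 10 merA and 10 merA-like genes, 2 merB genes,
#' and 16 pndr/dld-like decoys (divergent disulfide-oxidoreductase
#' relatives of MerA that reproduce the misannotation hazard of automated
#' pipelines).
#'
#' @return A tibble with columns `family`, `n`.
#' @export
default_planted <- function() {
  tibble(family = planted_families,
         n = c(10L, 10L, 10L, 2L, 16L))
}

#' Default sample design: 2 sites x 5 sampling periods x 3 replicates
#'
#' Emulates a 30-sample field design: two neighbouring brackish microbial
#' mats (EDB, SL) sampled over three campaigns, two of which include both
#' day and night time points, in triplicate.
#'
#' @return Character vector of 30 sample labels.
#' @export
default_samples <- function() {
  grid <- expand_grid(
    site = c("EDB", "SL"),
    period = c("Sep2011_day", "Apr2012_day", "Apr2012_night",
               "Sep2012_day", "Sep2012_night"),
    rep = 1:3)
  paste(grid$site, grid$period, paste0("r", grid$rep), sep = "_")
}

#' Configuration for the synthetic community generator
#'
#' Bundles and validates every knob of the generator. Defaults emulate the
#' study conditions the package is built around: a community of bins each
#' carrying one single-copy rpoB housekeeping gene, mercury genes planted
#' per [default_planted()], 30 structured samples, negative-binomial
#' transcript coverage (overdispersion is the norm in metatranscriptome
#' data), and log-uniform DNA coverage spanning the ~0.5-30 reads-per-base
#' range typical of medium-coverage MAGs.
#'
#' @param n_mags Number of MAGs (bins) to generate.
#' @param contigs_per_mag Length-2 integer range; each MAG draws its contig
#'   count uniformly from it.
#' @param mean_genes_per_contig Poisson mean for background genes per
#'   contig (floored at 1).
#' @param planted Tibble with columns `family`, `n`: how many instances of
#'   each planted family (vocabulary: `hgcAB_operon`, `merA`, `merA_like`,
#'   `merB`, `decoy_pndr_dld`). Instances are spread round-robin over MAGs.
#' @param samples Character vector of sample labels.
#' @param expression_rates Named nonnegative means of per-gene transcript
#'   coverage by family (`background` is the fallback); `rpoB` must be
#'   strictly positive.
#' @param dispersion Negative-binomial size parameter (> 0; smaller =
#'   more overdispersed).
#' @param dna_coverage_range Positive `c(lo, hi)` interval; per-MAG,
#'   per-sample base depths are drawn log-uniformly from it.
#' @param mutation_rate Per-residue substitution probability applied to
#'   planted genes (signature positions are protected on intact plants).
#' @param include_rpoB If `TRUE` (default) every MAG receives exactly one
#'   rpoB gene.
#' @param seed Integer seed; the whole community (and its transcript
#'   table) is a deterministic function of the configuration.
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_mags = 4, seed = 7)
#' cfg$mutation_rate
synth_config <- function(n_mags = 24,
                         contigs_per_mag = c(2, 4),
                         mean_genes_per_contig = 8,
                         planted = default_planted(),
                         samples = default_samples(),
                         expression_rates = c(background = 1, hgcA = 2,
                                              hgcB = 2, merA = 2,
                                              merA_like = 2, merB = 2,
                                              decoy_pndr_dld = 1, rpoB = 5),
                         dispersion = 2,
                         dna_coverage_range = c(0.5, 30),
                         mutation_rate = 0.02,
                         include_rpoB = TRUE,
                         seed = 1) {
  if (n_mags < 0 || n_mags != round(n_mags)) {
    abort("n_mags must be a nonnegative integer")
  }
  if (length(contigs_per_mag) != 2 || any(contigs_per_mag < 1) ||
      contigs_per_mag[1] > contigs_per_mag[2]) {
    abort("contigs_per_mag must be an increasing range of positive counts")
  }
  if (mean_genes_per_contig < 0) abort("mean_genes_per_contig must be >= 0")
  stopifnot(is.data.frame(planted),
            all(c("family", "n") %in% names(planted)))
  if (any(!planted$family %in% planted_families)) {
    abort(paste0("unknown planted family: ",
                 paste(setdiff(planted$family, planted_families),
                       collapse = ", ")))
  }
  if (any(planted$n < 0) || any(planted$n != round(planted$n))) {
    abort("planted counts must be nonnegative integers")
  }
  assert_nonneg(expression_rates, "expression_rates")
  if (is.null(names(expression_rates)) ||
      !"background" %in% names(expression_rates)) {
    abort("expression_rates must be named and include 'background'")
  }
  if (include_rpoB && (!"rpoB" %in% names(expression_rates) ||
                       expression_rates[["rpoB"]] <= 0)) {
    abort("expression_rates['rpoB'] must be strictly positive")
  }
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (length(dna_coverage_range) != 2 || any(dna_coverage_range <= 0) ||
      dna_coverage_range[1] > dna_coverage_range[2]) {
    abort("dna_coverage_range must be a positive increasing interval")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("mutation_rate must be in [0, 1]")
  }
  structure(
    list(n_mags = as.integer(n_mags),
         contigs_per_mag = as.integer(contigs_per_mag),
         mean_genes_per_contig = mean_genes_per_contig,
         planted = as_tibble(planted),
         samples = samples,
         expression_rates = expression_rates,
         dispersion = dispersion,
         dna_coverage_range = dna_coverage_range,
         mutation_rate = mutation_rate,
         include_rpoB = isTRUE(include_rpoB),
         seed = as.integer(seed)),
    class = "synth_config")
}

# Substitute residues at Bernoulli(rate) positions (never the protected
# ones), each to a uniformly chosen different residue.
mutate_protein <- function(protein, rate, protect = integer()) {
  if (rate == 0) return(protein)
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  idx <- setdiff(seq_along(ch), protect)
  hit <- idx[runif(length(idx)) < rate]
  for (i in hit) ch[i] <- sample(setdiff(aa_alphabet(), ch[i]), 1)
  paste(ch, collapse = "")
}

signature_positions <- function(family) {
  spec <- read_signature_spec()
  spec$position[spec$family == family]
}

# Ablate a signature: cysteines become serine, aspartate becomes
# asparagine (always a non-required residue at that position).
ablate_signature <- function(protein, spec_rows) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  swap <- c(C = "S", D = "N")
  for (k in seq_len(nrow(spec_rows))) {
    pos <- spec_rows$position[k]
    req <- substr(spec_rows$allowed_residues[k], 1, 1)
    ch[pos] <- swap[[req]] %||% "A"
  }
  paste(ch, collapse = "")
}

#' Plant one mercury-gene instance
#'
#' Produces the protein(s) for one planted family instance as a mutated
#' copy of the packaged synthetic reference:
#'
#' * `hgcAB_operon` — an hgcA and an hgcB protein destined for adjacent
#'   same-strand placement, with an intergenic distance drawn uniformly
#'   from 0-50 bp;
#' * `merA` / `merA_like` — a mercuric-reductase copy with the essential
#'   cysteine signature intact, or ablated (cysteines to serine);
#' * `merB` — an organomercury-lyase copy (C96/D99/C117/C159 intact unless
#'   `signature_status = "ablated"`);
#' * `decoy_pndr_dld` — a MerA copy mutated at 40% of its positions
#'   including every signature position: a divergent
#'   disulfide-oxidoreductase-like decoy that still scores well against
#'   the merA profile.
#'
#' Signature positions are never mutated on intact plants. Draws come from
#' the current RNG state (callers seed it; [generate_community()] does so
#' deterministically).
#'
#' @param family One of the planted-family vocabulary
#'   (`r paste(planted_families, collapse = ", ")`).
#' @param signature_status `"intact"` or `"ablated"`; `merA_like` forces
#'   `"ablated"`.
#' @param mutation_rate Per-residue substitution probability.
#' @return A list of class `planted_gene`: `family`, `signature_status`,
#'   `genes` (tibble with `role`, `protein`), `intergenic_bp` (`NA` unless
#'   an operon).
#' @export
#' @examples
#' set.seed(1)
#' plant_gene("merA", mutation_rate = 0)$genes$protein ==
#'   unname(ref_proteins("merA"))
plant_gene <- function(family, signature_status = c("intact", "ablated"),
                       mutation_rate = 0) {
  if (!family %in% planted_families) {
    abort(paste0("unknown planted family: ", family))
  }
  signature_status <- match.arg(signature_status)
  spec <- read_signature_spec()

  if (family == "hgcAB_operon") {
    a <- mutate_protein(unname(ref_proteins("hgcA")), mutation_rate)
    b <- mutate_protein(unname(ref_proteins("hgcB")), mutation_rate)
    return(structure(list(
      family = family, signature_status = signature_status,
      genes = tibble(role = c("hgcA", "hgcB"), protein = c(a, b)),
      intergenic_bp = sample(0:50, 1)), class = "planted_gene"))
  }

  base_family <- switch(family, merA_like = "merA",
                        decoy_pndr_dld = "merA", family)
  ref <- unname(ref_proteins(base_family))
  spec_rows <- spec[spec$family == base_family, ]
  role <- switch(family, merA_like = "merA", decoy_pndr_dld = "decoy",
                 family)

  if (family == "decoy_pndr_dld") {
    n <- nchar(ref)
    sig <- spec_rows$position
    n_mut <- max(round(0.4 * n), length(sig))
    extra <- sample(setdiff(seq_len(n), sig), n_mut - length(sig))
    ch <- strsplit(ref, "", fixed = TRUE)[[1]]
    for (i in c(sig, extra)) ch[i] <- sample(setdiff(aa_alphabet(), ch[i]), 1)
    prot <- paste(ch, collapse = "")
    status <- "ablated"
  } else {
    status <- if (family == "merA_like") "ablated" else signature_status
    prot <- ref
    if (status == "ablated" && nrow(spec_rows) > 0) {
      prot <- ablate_signature(prot, spec_rows)
    }
    prot <- mutate_protein(prot, mutation_rate, protect = spec_rows$position)
  }

  structure(list(family = family, signature_status = status,
                 genes = tibble(role = role, protein = prot),
                 intergenic_bp = NA_integer_),
            class = "planted_gene")
}

random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a ground-truth-labeled synthetic community
#'
#' Builds a full in-silico community: MAGs with contigs, background genes
#' of random composition (maximally unlike any profile, so background
#' false positives are structurally absent), one rpoB gene per MAG,
#' planted mercury genes per the configuration, per-contig DNA coverage,
#' and a CheckM-style quality table. Planted instances are spread
#' round-robin across MAGs; hgcAB pairs are placed adjacently on the same
#' strand. The result is a deterministic function of the configuration
#' (including its seed); with `dir` set, all community files are written
#' and two identical runs produce byte-identical files.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, [write_community()] is
#'   called on the result.
#' @return An object of class `synth_community`: list with `genes`
#'   (per-gene tibble: id, MAG, contig, coordinates, strand, protein,
#'   family, signature status, operon partner), `contigs`, `mag_quality`,
#'   `dna_coverage`, `truth` (planted ground truth), `config`, and `dir`
#'   (path or `NA`).
#' @export
#' @examples
#' comm <- generate_community(synth_config(n_mags = 3, seed = 42))
#' nrow(comm$truth)
generate_community <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(derive_seed(config$seed, "community"))

  empty_genes <- tibble(
    gene_id = character(), mag_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    protein = character(), family = character(),
    signature_status = character(), operon_partner = character())
  empty_truth <- tibble(gene_id = character(), family = character(),
                        signature_status = character(),
                        operon_partner = character(), mag_id = character())

  if (config$n_mags == 0) {
    comm <- structure(
      list(genes = empty_genes,
           contigs = tibble(contig_id = character(), mag_id = character(),
                            length = integer(), sequence = character()),
           mag_quality = tibble(mag_id = character(), completeness = double(),
                                contamination = double()),
           dna_coverage = tibble(mag_id = character(), contig_id = character(),
                                 sample_id = character(), mean_depth = double()),
           truth = empty_truth, config = config, dir = NA_character_),
      class = "synth_community")
    if (!is.null(dir)) comm <- write_community(comm, dir)
    return(comm)
  }

  mag_ids <- sprintf("mag%03d", seq_len(config$n_mags))
  mag_quality <- tibble(
    mag_id = mag_ids,
    completeness = round(runif(config$n_mags, 55, 99), 2),
    contamination = round(runif(config$n_mags, 0, 4.5), 2))

  # plan planted instances and their hosts (round-robin over MAGs)
  plant_plan <- config$planted[rep(seq_len(nrow(config$planted)),
                                   config$planted$n), "family"]
  n_plants <- nrow(plant_plan)
  plant_plan$host <- mag_ids[((seq_len(n_plants) - 1L) %% config$n_mags) + 1L]

  # one unit = one or two genes placed consecutively (operon = one unit)
  units_by_mag <- setNames(vector("list", config$n_mags), mag_ids)
  for (m in mag_ids) {
    contig_choices <- config$contigs_per_mag[1]:config$contigs_per_mag[2]
    n_contigs <- contig_choices[sample.int(length(contig_choices), 1)]
    mag_units <- list()
    for (ci in seq_len(n_contigs)) {
      n_bg <- max(1L, rpois(1, config$mean_genes_per_contig))
      for (g in seq_len(n_bg)) {
        mag_units[[length(mag_units) + 1L]] <- list(
          contig = ci, family = "background", signature_status = NA_character_,
          genes = tibble(role = "background",
                         protein = random_protein(sample(150:450, 1))),
          intergenic_bp = NA_integer_)
      }
    }
    if (config$include_rpoB) {
      mag_units[[length(mag_units) + 1L]] <- list(
        contig = 1L, family = "rpoB", signature_status = "intact",
        genes = tibble(role = "rpoB",
                       protein = mutate_protein(unname(ref_proteins("rpoB")),
                                                config$mutation_rate)),
        intergenic_bp = NA_integer_)
    }
    for (k in which(plant_plan$host == m)) {
      pg <- plant_gene(plant_plan$family[k],
                       mutation_rate = config$mutation_rate)
      mag_units[[length(mag_units) + 1L]] <- list(
        contig = sample(seq_len(n_contigs), 1), family = pg$family,
        signature_status = pg$signature_status, genes = pg$genes,
        intergenic_bp = pg$intergenic_bp)
    }
    units_by_mag[[m]] <- mag_units
  }

  # lay out coordinates contig by contig
  gene_rows <- list()
  contig_rows <- list()
  truth_rows <- list()
  for (m in mag_ids) {
    mag_units <- units_by_mag[[m]]
    contigs <- sort(unique(vapply(mag_units, function(u) u$contig,
                                  integer(1))))
    for (ci in contigs) {
      contig_id <- sprintf("%s_c%02d", m, ci)
      units <- mag_units[vapply(mag_units, function(u) u$contig == ci,
                                logical(1))]
      units <- units[sample(length(units))]  # shuffle order along the contig
      pos <- 101L
      gi <- 0L
      for (u in units) {
        strand <- sample(c("+", "-"), 1)
        n_genes <- nrow(u$genes)
        # on "-" the downstream (3') gene sits at lower coordinates, so an
        # operon lays its second gene (hgcB) first
        order_idx <- if (n_genes == 2 && strand == "-") c(2L, 1L)
        else seq_len(n_genes)
        placed_ids <- character(n_genes)
        for (j in order_idx) {
          gi <- gi + 1L
          nt_len <- 3L * (nchar(u$genes$protein[j]) + 1L)
          gene_id <- sprintf("%s_g%03d", contig_id, gi)
          placed_ids[j] <- gene_id
          gene_rows[[length(gene_rows) + 1L]] <- tibble(
            gene_id = gene_id, mag_id = m, contig_id = contig_id,
            start = pos, end = pos + nt_len - 1L, strand = strand,
            protein = u$genes$protein[j],
            family = if (u$family == "background") "background"
            else u$genes$role[j],
            signature_status = u$signature_status,
            operon_partner = NA_character_)
          gap <- if (n_genes == 2 && j != order_idx[n_genes]) {
            u$intergenic_bp
          } else {
            sample(60:300, 1)
          }
          pos <- pos + nt_len + as.integer(gap)
        }
        if (u$family %in% planted_families || u$family == "rpoB") {
          partner <- if (n_genes == 2) placed_ids[2] else NA_character_
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            gene_id = placed_ids[1], family = u$family,
            signature_status = u$signature_status,
            operon_partner = partner, mag_id = m)
          if (n_genes == 2) {
            # cross-link partner on the gene table
            idx <- length(gene_rows) - n_genes + seq_len(n_genes)
            for (ii in idx) {
              gene_rows[[ii]]$operon_partner <-
                setdiff(placed_ids, gene_rows[[ii]]$gene_id)
            }
          }
        }
      }
      contig_len <- pos + 100L
      contig_rows[[length(contig_rows) + 1L]] <- tibble(
        contig_id = contig_id, mag_id = m, length = contig_len,
        sequence = random_dna(contig_len))
    }
  }

  genes <- list_rbind(gene_rows)
  contigs <- list_rbind(contig_rows)
  truth <- if (length(truth_rows)) list_rbind(truth_rows) else empty_truth

  # per-MAG, per-sample base depth (log-uniform), with mild per-contig noise
  lo <- log(config$dna_coverage_range[1])
  hi <- log(config$dna_coverage_range[2])
  cov_grid <- expand_grid(mag_id = mag_ids, sample_id = config$samples)
  cov_grid$base_depth <- exp(runif(nrow(cov_grid), lo, hi))
  dna_coverage <- left_join(contigs[, c("contig_id", "mag_id")],
                            cov_grid, by = "mag_id",
                            relationship = "many-to-many")
  dna_coverage$mean_depth <- dna_coverage$base_depth *
    runif(nrow(dna_coverage), 0.85, 1.15)
  dna_coverage <- dna_coverage[, c("mag_id", "contig_id", "sample_id",
                                   "mean_depth")]

  comm <- structure(
    list(genes = genes, contigs = contigs, mag_quality = mag_quality,
         dna_coverage = as_tibble(dna_coverage), truth = truth,
         config = config, dir = NA_character_),
    class = "synth_community")
  if (!is.null(dir)) comm <- write_community(comm, dir)
  comm
}

#' @export
print.synth_community <- function(x, ...) {
  cat(sprintf(paste0("<synth_community> %d MAGs, %d contigs, %d genes ",
                     "(%d planted), %d samples\n"),
              nrow(x$mag_quality), nrow(x$contigs), nrow(x$genes),
              nrow(x$truth), length(x$config$samples)))
  invisible(x)
}

#' Simulate per-gene, per-sample transcript coverage
#'
#' Draws negative-binomial transcript coverage for every gene in every
#' sample. Each gene's mean is looked up from the configured per-family
#' expression rates (falling back to the `background` rate); the common
#' dispersion parameter controls overdispersion. A zero rate yields zero
#' coverage in every sample. Draws are seeded from the configuration, so
#' the table is reproducible independently of [generate_community()].
#'
#' @param community A [generate_community()] result, or any tibble with
#'   columns `gene_id` and `family`.
#' @param config A [synth_config()]; defaults to the community's own.
#' @param rates Optional named per-family rate override.
#' @return A tibble: `gene_id`, `sample_id`, `transcript_coverage`.
#' @export
#' @examples
#' comm <- generate_community(synth_config(n_mags = 2, seed = 3))
#' rna <- simulate_transcripts(comm)
#' nrow(rna) == nrow(comm$genes) * 30
simulate_transcripts <- function(community, config = NULL, rates = NULL) {
  genes <- if (inherits(community, "synth_community")) community$genes
  else as_tibble(community)
  stopifnot(all(c("gene_id", "family") %in% names(genes)))
  config <- config %||%
    (if (inherits(community, "synth_community")) community$config)
  if (is.null(config)) abort("config required when community is a tibble")
  rates <- rates %||% config$expression_rates
  assert_nonneg(rates, "expression rates")

  gene_rate <- rates[genes$family]
  gene_rate[is.na(gene_rate)] <- rates[["background"]]

  withr::local_seed(derive_seed(config$seed, "transcripts"))
  grid <- expand_grid(gene_id = genes$gene_id,
                      sample_id = config$samples)
  grid$transcript_coverage <- rnbinom(
    nrow(grid),
    mu = rep(unname(gene_rate), each = length(config$samples)),
    size = config$dispersion)
  as_tibble(grid)
}
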