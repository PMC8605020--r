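test_that("synth_config validates its inputs", {
  expect_s3_class(synth_config(n_mags = 2), "synth_config")
  expect_error(synth_config(n_mags = -1), "nonnegative")
  expect_error(synth_config(mutation_rate = 1.5), "0, 1")
  expect_error(synth_config(dispersion = 0), "dispersion")
  expect_error(synth_config(dna_coverage_range = c(2, 1)), "interval")
  expect_error(
    synth_config(planted = tibble::tibble(family = "nope", n = 1L)),
    "unknown planted family")
  expect_error(
    synth_config(expression_rates = c(background = 1, rpoB = 0)),
    "rpoB")
})

test_that("an empty community is well-formed and writes empty files", {
  dir <- withr::local_tempdir()
  comm <- generate_community(synth_config(n_mags = 0, seed = 5), dir)
  expect_equal(nrow(comm$genes), 0)
  expect_equal(nrow(comm$truth), 0)
  expect_true(file.exists(file.path(dir, "mag_quality.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
})

test_that("same config and seed produce byte-identical community files", {
  cfg <- synth_config(n_mags = 3, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_community(cfg, d1)
  generate_community(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = paste("bytes of", f))
  }
})

test_that("ground truth conserves configured plant counts", {
  for (seed in c(1, 2)) {
    planted <- tibble::tibble(
      family = c("hgcAB_operon", "merA", "merA_like"),
      n = c(5L, 3L, 2L))
    comm <- generate_community(
      synth_config(n_mags = 4, planted = planted, seed = seed))
    counts <- table(comm$truth$family)
    expect_equal(unname(counts[["hgcAB_operon"]]), 5)
    expect_equal(unname(counts[["merA"]]), 3)
    expect_equal(unname(counts[["merA_like"]]), 2)
    # one rpoB per MAG
    expect_equal(unname(counts[["rpoB"]]), 4)
    expect_false(anyDuplicated(comm$truth$gene_id) > 0)
  }
})

test_that("plant_gene at zero mutation reproduces the reference exactly", {
  set.seed(1)
  pg <- plant_gene("merA", mutation_rate = 0)
  expect_identical(pg$genes$protein, unname(ref_proteins("merA")))
  op <- plant_gene("hgcAB_operon", mutation_rate = 0)
  expect_identical(op$genes$role, c("hgcA", "hgcB"))
  expect_true(op$intergenic_bp >= 0 && op$intergenic_bp <= 50)
  expect_error(plant_gene("notafamily"), "unknown")
})

test_that("ablated plants carry serine at required cysteine positions", {
  set.seed(2)
  pg <- plant_gene("merA", signature_status = "ablated", mutation_rate = 0)
  spec <- dplyr::filter(read_signature_spec(), family == "merA")
  residues <- strsplit(pg$genes$protein, "")[[1]]
  expect_true(all(residues[spec$position] == "S"))
  # and a merA_like plant is ablated by definition
  pl <- plant_gene("merA_like", mutation_rate = 0)
  expect_identical(pl$signature_status, "ablated")
})

test_that("observed substitution fraction matches the mutation rate", {
  set.seed(42)
  rate <- 0.05
  ref <- unname(ref_proteins("merB"))
  spec <- dplyr::filter(read_signature_spec(), family == "merB")
  free <- nchar(ref) - nrow(spec)  # signature positions are protected
  n_plants <- 1000
  n_sub <- 0
  ref_chars <- strsplit(ref, "")[[1]]
  for (i in seq_len(n_plants)) {
    p <- plant_gene("merB", mutation_rate = rate)
    n_sub <- n_sub + sum(strsplit(p$genes$protein, "")[[1]] != ref_chars)
  }
  n_trials <- n_plants * free
  se <- sqrt(rate * (1 - rate) / n_trials)
  expect_lt(abs(n_sub / n_trials - rate), 3 * se)
})

test_that("decoy plants diverge ~40% from MerA incl. all signatures", {
  set.seed(3)
  ref <- strsplit(unname(ref_proteins("merA")), "")[[1]]
  spec <- dplyr::filter(read_signature_spec(), family == "merA")
  pg <- plant_gene("decoy_pndr_dld")
  ch <- strsplit(pg$genes$protein, "")[[1]]
  expect_equal(sum(ch != ref), round(0.4 * length(ref)))
  expect_true(all(ch[spec$position] != ref[spec$position]))
})

test_that("transcript simulation is seeded, NB-distributed and zero-safe", {
  cfg <- synth_config(n_mags = 2, seed = 9)
  comm <- generate_community(cfg)
  r1 <- simulate_transcripts(comm)
  r2 <- simulate_transcripts(comm)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), nrow(comm$genes) * length(cfg$samples))
  expect_true(all(r1$transcript_coverage >= 0))

  # zero rate => zero coverage everywhere
  zero <- simulate_transcripts(
    comm, rates = c(background = 0, rpoB = 1e-12))
  bg_ids <- comm$genes$gene_id[comm$genes$family == "background"]
  expect_true(all(zero$transcript_coverage[zero$gene_id %in% bg_ids] == 0))

  expect_error(simulate_transcripts(comm, rates = c(background = -1)),
               "non-negative")
})

test_that("intact plants pass and ablated plants fail validation at rate 0", {
  comm <- generate_community(noiseless_config(seed = 11, decoys = 0L))
  spec <- read_signature_spec()
  for (i in seq_len(nrow(comm$truth))) {
    row <- comm$truth[i, ]
    if (!row$family %in% c("merA", "merA_like", "merB")) next
    fam <- if (row$family == "merA_like") "merA" else row$family
    prot <- comm$genes$protein[comm$genes$gene_id == row$gene_id]
    res <- check_signature(prot, dplyr::filter(spec, family == fam))
    expect_identical(res$pass, row$signature_status == "intact",
                     label = paste(row$family, row$gene_id))
  }
})
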