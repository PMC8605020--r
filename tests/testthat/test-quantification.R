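test_that("MAG quality filter applies strict 50%/5% bounds", {
  mags <- tibble::tibble(
    mag_id = c("bin506", "at_completeness_bound", "at_contamination_bound",
               "good"),
    completeness = c(57.45, 50.0, 80, 75),
    contamination = c(2.65, 1.0, 5.0, 4.99))
  kept <- quality_filter_mags(mags)
  expect_setequal(kept$mag_id, c("bin506", "good"))
  # idempotent and order-preserving
  expect_identical(quality_filter_mags(kept), kept)
  expect_identical(kept$mag_id,
                   mags$mag_id[mags$mag_id %in% kept$mag_id])
  expect_error(quality_filter_mags(tibble::tibble(mag_id = "x")), "columns")
  expect_error(
    quality_filter_mags(tibble::tibble(mag_id = "x", completeness = NA,
                                       contamination = 1)),
    "missing")
})

test_that("MAG coverage is the length-weighted mean of contig depths", {
  one <- tibble::tibble(mag_id = "m", length = 500, mean_depth = 2)
  expect_equal(mag_coverage(one)$coverage, 2)

  two <- tibble::tibble(mag_id = "m", length = c(100, 300),
                        mean_depth = c(2, 4))
  expect_equal(mag_coverage(two)$coverage, 3.5)

  # linear in depth
  scaled <- dplyr::mutate(two, mean_depth = mean_depth * 7)
  expect_equal(mag_coverage(scaled)$coverage, 7 * 3.5)

  expect_error(mag_coverage(two[0, ]), "non-empty")
  expect_error(
    mag_coverage(tibble::tibble(mag_id = "m", length = 0, mean_depth = 1)),
    "> 0")
})

test_that("abundance summary classes MAGs against the community mean", {
  ab <- abundance_summary(tibble::tibble(mag_id = c("a", "b", "c"),
                                         coverage = c(1, 2, 3)))
  expect_equal(ab$stats$mean, 2)
  expect_equal(ab$stats$median, 2)
  expect_equal(ab$stats$max, 3)
  expect_identical(
    ab$mags$abundance_class[ab$mags$mag_id == "c"], "above_average")
  expect_identical(
    ab$mags$abundance_class[ab$mags$mag_id == "a"], "below_average")

  # a MAG above the community mean is above_average
  comm <- abundance_summary(tibble::tibble(
    mag_id = c("bin805", "rest1", "rest2"),
    coverage = c(4.20, 3.5, 2.8)))
  expect_identical(
    comm$mags$abundance_class[comm$mags$mag_id == "bin805"],
    "above_average")

  # strict inequality: all-equal coverages give no above_average
  tie <- abundance_summary(tibble::tibble(mag_id = c("a", "b"),
                                          coverage = c(2, 2)))
  expect_false(any(tie$mags$abundance_class == "above_average"))
  expect_error(abundance_summary(tibble::tibble(mag_id = character(),
                                                coverage = double())),
               "non-empty")
})

test_that("rpoB normalization assigns ratios and categories", {
  res <- normalize_to_rpoB(c(0, 5, 10, 1, 3), c(7, 5, 2, 10, 0))
  expect_equal(res$ratio[1:4], c(0, 1, 5, 0.1))
  expect_identical(as.character(res$category),
                   c("not_expressed", "similar", "higher", "lower",
                     "undetermined"))
  expect_true(is.na(res$ratio[5]))
  # gene 0 with rpoB 0 is not_expressed, not undetermined
  both0 <- normalize_to_rpoB(0, 0)
  expect_identical(as.character(both0$category), "not_expressed")
  expect_error(normalize_to_rpoB(-1, 1), "non-negative")
  expect_error(normalize_to_rpoB(1, 1, similar_band = c(0, 2)), "band")

  # scale invariance of ratios and categories
  g <- c(0, 2, 8, 3); r <- c(4, 4, 4, 4)
  a <- normalize_to_rpoB(g, r)
  b <- normalize_to_rpoB(g * 13, r * 13)
  expect_equal(a$ratio, b$ratio)
  expect_identical(a$category, b$category)
})

test_that("summed profiles pool samples before normalizing", {
  expr <- tibble::tibble(
    mag_id = "m", gene_id = rep(c("g1", "rpoB"), each = 2),
    sample_id = rep(c("s1", "s2"), 2),
    transcript_coverage = c(2, 3, 1, 4),
    rpoB_coverage = c(1, 4, 1, 4))
  out <- summed_pathway_profile(expr)
  expect_equal(out$ratio[out$gene_id == "g1"], 5 / 5)
  expect_identical(as.character(out$category[out$gene_id == "g1"]),
                   "similar")

  # single sample: identical to the per-sample ratio
  single <- dplyr::filter(expr, sample_id == "s1")
  out1 <- summed_pathway_profile(single)
  per <- normalize_to_rpoB(single$transcript_coverage[1],
                           single$rpoB_coverage[1])
  expect_equal(out1$ratio[out1$gene_id == "g1"], per$ratio)

  # scaling all coverages leaves summed ratios unchanged
  scaled <- dplyr::mutate(expr,
                          transcript_coverage = transcript_coverage * 9,
                          rpoB_coverage = rpoB_coverage * 9)
  expect_equal(summed_pathway_profile(scaled)$ratio, out$ratio)

  expect_error(
    summed_pathway_profile(dplyr::mutate(expr, mag_id = c("m", "m", "n", "n"))),
    "single MAG")
})

test_that("column_mean_sd computes mean and n-1 standard deviation", {
  ms <- column_mean_sd(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sd, 1)
  one <- column_mean_sd(7)
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd))
  tab <- column_mean_sd(mat_mag_summary(), "n_genes_expressed")
  expect_equal(tab$n, 23)
  expect_error(column_mean_sd(numeric()), "at least one")
})

test_that("Bray-Curtis similarity matches its formula and vegan", {
  expect_equal(bray_curtis_similarity(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(bray_curtis_similarity(c(2, 1, 0), c(1, 1, 1)),
               100 * 4 / 6)
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis_similarity(1, c(1, 2)), "equal length")

  set.seed(5)
  for (k in 1:10) {
    a <- rpois(8, 20); b <- rpois(8, 20)
    ours <- bray_curtis_similarity(a, b)
    veg <- 100 * (1 - as.numeric(vegan::vegdist(rbind(a, b),
                                                method = "bray")))
    expect_equal(ours, veg)
    expect_equal(ours, bray_curtis_similarity(b, a))  # symmetry
    expect_gte(ours, 0); expect_lte(ours, 100)        # bounds
  }
})
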