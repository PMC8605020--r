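test_that("identity and all-gap alignments score as forced by the model", {
  a <- global_align("ACDE", "ACDE")
  expect_equal(a$score, 4 + 9 + 6 + 5)  # BLOSUM62 diagonal
  expect_identical(a$aligned_query, "ACDE")

  b <- global_align("", "ACD")
  expect_equal(b$score, -(11 + 3 * 1))
  expect_identical(b$aligned_query, "---")
  expect_identical(b$aligned_reference, "ACD")

  expect_error(global_align("AC1", "ACD"), "substitution matrix")
})

test_that("DP score matches brute-force enumeration on random short pairs", {
  set.seed(11)
  sub <- blosum62()
  for (k in 1:60) {
    q <- random_peptide(sample(1:5, 1), alphabet = c("A", "C", "D"))
    r <- random_peptide(sample(1:5, 1), alphabet = c("A", "C", "D"))
    qi <- match(strsplit(q, "")[[1]], rownames(sub))
    ri <- match(strsplit(r, "")[[1]], rownames(sub))
    dp <- mercmags:::nw_affine_cpp(qi, ri, sub, 11, 1)$score
    bf <- mercmags:::enum_align_score_cpp(qi, ri, sub, 11, 1)
    expect_equal(dp, bf, label = paste(q, "vs", r))
  }
})

test_that("aligner agrees with an independent implementation on proteins", {
  set.seed(12)
  sub <- blosum62()
  for (k in 1:10) {
    q <- random_peptide(sample(20:80, 1))
    r <- random_peptide(sample(20:80, 1))
    ours <- global_align(q, r)$score
    theirs <- Biostrings::pairwiseAlignment(
      q, r, substitutionMatrix = sub, gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(ours, theirs)
  }
})

test_that("degapping aligned strings recovers the inputs, always", {
  set.seed(13)
  for (k in 1:20) {
    q <- random_peptide(sample(0:30, 1))
    r <- random_peptide(sample(1:30, 1))
    a <- global_align(q, r)
    expect_identical(gsub("-", "", a$aligned_query), q)
    expect_identical(gsub("-", "", a$aligned_reference), r)
    expect_equal(nchar(a$aligned_query), nchar(a$aligned_reference))
    # no column may be gap in both
    qg <- strsplit(a$aligned_query, "")[[1]] == "-"
    rg <- strsplit(a$aligned_reference, "")[[1]] == "-"
    expect_false(any(qg & rg))
  }
})

test_that("alignment and signature checks are deterministic", {
  q <- paste0(substr(ref_proteins("merB"), 1, 100), "AAAA")
  a1 <- global_align(q, ref_proteins("merB"))
  a2 <- global_align(q, ref_proteins("merB"))
  expect_identical(a1, a2)
  spec <- dplyr::filter(read_signature_spec(), family == "merB")
  r1 <- check_signature(ref_proteins("merB"), spec)
  r2 <- check_signature(ref_proteins("merB"), spec)
  expect_identical(r1$positions, r2$positions)
})

test_that("reference positions map through gaps correctly", {
  ref <- "ACDEFGHIKLMN"
  ident <- global_align(ref, ref)
  m <- map_reference_positions(ident, c(1, 5, 12))
  expect_equal(m$query_position, c(1, 5, 12))
  expect_false(any(m$deleted))

  # two-residue query insertion before reference position 10:
  # positions at or after the insertion shift by +2 on the query
  ins <- structure(list(aligned_query = "ACDEFGHIKWWLMN",
                        aligned_reference = "ACDEFGHIK--LMN",
                        score = 0), class = "pairwise_alignment")
  m2 <- map_reference_positions(ins, c(9, 10))
  expect_equal(m2$query_position, c(9, 12))

  # reference position in a query-gap column is deleted
  del <- structure(list(aligned_query = "AC--FG",
                        aligned_reference = "ACDEFG",
                        score = 0), class = "pairwise_alignment")
  m3 <- map_reference_positions(del, c(3, 5))
  expect_identical(m3$deleted, c(TRUE, FALSE))
  expect_true(is.na(m3$query_position[1]))

  expect_error(map_reference_positions(ident, 99), "beyond")
})

test_that("merB signature check follows the curation rules", {
  spec <- dplyr::filter(read_signature_spec(), family == "merB")
  ref <- unname(ref_proteins("merB"))

  self <- check_signature(ref, spec)
  expect_true(self$pass)
  expect_identical(self$classification, "merB")

  # single ablation C96S: fails, reporting the serine
  ch <- strsplit(ref, "")[[1]]
  ch[96] <- "S"
  ablated <- check_signature(paste(ch, collapse = ""), spec)
  expect_false(ablated$pass)
  expect_identical(
    ablated$positions$found[ablated$positions$reference_position == 96], "S")
  expect_identical(ablated$classification, "merB_like")

  # poly-alanine of reference length fails at every required position
  poly <- check_signature(strrep("A", nchar(ref)), spec)
  expect_false(any(poly$positions$ok))
})

test_that("truncated candidates are indeterminate, never family-like", {
  spec <- dplyr::filter(read_signature_spec(), family == "merA")
  ref <- unname(ref_proteins("merA"))
  # drop the C-terminal third: positions 558/559 fall beyond the fragment
  frag <- substr(ref, 1, 400)
  res <- check_signature(frag, spec)
  expect_identical(res$classification, "indeterminate")
  expect_identical(res$reason, "truncated")
})

test_that("merA classification separates merA, merA-like and decoys", {
  set.seed(17)
  expect_identical(classify_merA(ref_proteins("merA"))$classification,
                   "merA")
  abl <- plant_gene("merA", "ablated", mutation_rate = 0)$genes$protein
  expect_identical(classify_merA(abl)$classification, "merA_like")
  dec <- plant_gene("decoy_pndr_dld")$genes$protein
  res <- classify_merA(dec)
  expect_identical(res$classification, "indeterminate")
  expect_identical(res$reason, "divergent_homolog")
})

test_that("a mixed merA fixture classifies 10 + 10 exactly", {
  set.seed(19)
  intact <- replicate(10, plant_gene("merA", mutation_rate = 0.02)$genes$protein)
  ablated <- replicate(10, plant_gene("merA_like",
                                      mutation_rate = 0.02)$genes$protein)
  calls <- vapply(c(intact, ablated),
                  function(p) classify_merA(p)$classification, character(1))
  expect_equal(sum(calls == "merA"), 10)
  expect_equal(sum(calls == "merA_like"), 10)
})

test_that("hgcB operon context follows coordinates, strand and distance", {
  genes <- tibble::tibble(
    gene_id = c("a", "b"),
    start = c(1000, 2050), end = c(1996, 2300),
    strand = c("+", "+"))
  ctx <- find_hgcB_downstream("a", genes, hgcB_ids = "b",
                              max_intergenic = 200)
  expect_true(ctx$found)
  expect_equal(ctx$intergenic_distance, 53)  # 2050 - 1996 - 1

  # opposite strand: absent
  genes2 <- dplyr::mutate(genes, strand = c("+", "-"))
  expect_false(find_hgcB_downstream("a", genes2, "b")$found)

  # beyond max_intergenic: absent
  expect_false(find_hgcB_downstream("a", genes, "b",
                                    max_intergenic = 50)$found)

  # intervening non-hgcB gene: absent
  genes3 <- tibble::tibble(
    gene_id = c("a", "x", "b"),
    start = c(1000, 2000, 2050), end = c(1996, 2040, 2300),
    strand = "+")
  expect_false(find_hgcB_downstream("a", genes3, "b")$found)

  # minus-strand hgcA: downstream is at lower coordinates
  genes4 <- tibble::tibble(
    gene_id = c("b", "a"),
    start = c(100, 500), end = c(400, 900),
    strand = "-")
  ctx4 <- find_hgcB_downstream("a", genes4, "b")
  expect_true(ctx4$found)
  expect_equal(ctx4$intergenic_distance, 99)  # 500 - 400 - 1

  expect_error(find_hgcB_downstream("zz", genes, "b"), "not on")
})

test_that("noiseless operon recovery matches the planted truth exactly", {
  comm <- generate_community(noiseless_config(seed = 23))
  hits <- screen_families(comm$genes[, c("gene_id", "protein")],
                          family_profiles(c("hgcA", "hgcB")))
  ctx <- operon_contexts(hits$gene_id[hits$family == "hgcA"],
                         comm$genes,
                         hits$gene_id[hits$family == "hgcB"])
  truth <- comm$truth[comm$truth$family == "hgcAB_operon", ]
  found <- ctx[ctx$found, ]
  expect_setequal(found$hgcA_gene_id, truth$gene_id)
  expect_identical(
    setNames(found$hgcB_gene_id, found$hgcA_gene_id)[truth$gene_id],
    setNames(truth$operon_partner, truth$gene_id))
  expect_true(all(found$intergenic_distance <= 50))
})
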