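test_that("genotype classes score 5/3/0 against the reference", {
  expect_equal(genotype_points(c("HOM_ALT", "HET", "HOM_REF", "MISSING")),
               c(5L, 3L, 0L, 0L))
  expect_error(genotype_points("HEMI"), "HOM_REF/HET/HOM_ALT/MISSING")
})

one_site_geno <- function(calls) {
  m <- matrix(calls, ncol = 1,
              dimnames = list(sprintf("A%02d", seq_along(calls)), NULL))
  geno_from_matrix(m)
}

test_that("segregation scores are positive-group minus negative-group point sums", {
  g <- one_site_geno(c("HOM_ALT", "HET", "HOM_REF", "HOM_REF"))
  res <- segregate(g, grouping_of("c", c("A01", "A02"), c("A03", "A04")))
  expect_equal(res$pos_points, 8L)
  expect_equal(res$neg_points, 0L)
  expect_equal(res$score, 8L)
  expect_equal(res$exclusivity, "PERFECT")

  all_ref <- one_site_geno(rep("HOM_REF", 4))
  expect_equal(segregate(all_ref,
                         grouping_of("c", c("A01", "A02"), c("A03", "A04")))$score, 0L)

  neg_het <- one_site_geno(c("HOM_REF", "HOM_REF", "HET", "HOM_REF"))
  res3 <- segregate(neg_het, grouping_of("c", c("A01", "A02"), c("A03", "A04")))
  expect_equal(res3$score, -3L)
  expect_equal(res3$exclusivity, "NON_EXCLUSIVE")
})

test_that("exclusivity distinguishes perfect, exclusive and non-exclusive sites", {
  gr <- grouping_of("c", c("A01", "A02"), c("A03", "A04"))
  classify <- function(calls) segregate(one_site_geno(calls), gr)$exclusivity
  expect_equal(classify(c("HET", "HOM_ALT", "HOM_REF", "HOM_REF")), "PERFECT")
  expect_equal(classify(c("HET", "HOM_REF", "HOM_REF", "HOM_REF")), "EXCLUSIVE")
  expect_equal(classify(c("HET", "HET", "HET", "HOM_REF")), "NON_EXCLUSIVE")
  # MISSING neither carries nor completes a perfect pattern
  expect_equal(classify(c("HET", "MISSING", "HOM_REF", "HOM_REF")), "EXCLUSIVE")
  expect_equal(classify(c("HOM_REF", "HOM_REF", "MISSING", "MISSING")),
               "NON_EXCLUSIVE")
})

test_that("grouped animals absent from the matrix raise a named error", {
  g <- one_site_geno(c("HET", "HOM_REF"))
  expect_error(segregate(g, grouping_of("c", "A01", c("A02", "A99"))), "A99")
})

test_that("scores respect their bounds and the maximum is attained only at saturation", {
  set.seed(21)
  for (i in 1:100) {
    n_pos <- sample(1:5, 1)
    n_neg <- sample(1:8, 1)
    calls <- sample(c("HOM_REF", "HET", "HOM_ALT", "MISSING"),
                    n_pos + n_neg, replace = TRUE)
    g <- one_site_geno(calls)
    ids <- sprintf("A%02d", seq_along(calls))
    res <- segregate(g, grouping_of("c", ids[1:n_pos], ids[-(1:n_pos)]))
    expect_gte(res$score, -5L * n_neg)
    expect_lte(res$score, 5L * n_pos)
    saturated <- all(calls[1:n_pos] == "HOM_ALT") &&
      all(calls[-(1:n_pos)] == "HOM_REF")
    expect_equal(res$score == 5L * n_pos && res$neg_points == 0L &&
                   res$pos_points == 5L * n_pos, saturated)
  }
})

test_that("vectorised scoring matches the brute-force oracle", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    g <- random_genotype_tbl(n_animals = n, n_sites = 5, seed = 1000 + i)
    ids <- sprintf("A%02d", 1:n)
    n_pos <- sample(1:(n - 1), 1)
    pos <- sample(ids, n_pos)
    neg <- setdiff(ids, pos)
    res <- segregate(g, grouping_of("c", pos, neg))
    for (s in unique(g$site_id)) {
      calls_pos <- g$gt[g$animal_id %in% pos & g$site_id == s]
      calls_neg <- g$gt[g$animal_id %in% neg & g$site_id == s]
      exp <- oracle_site_score(calls_pos, calls_neg)
      row <- res[res$site_id == s, ]
      expect_equal(row$score, exp$score)
      expect_equal(row$pos_points, exp$pos_points)
      expect_equal(row$exclusivity, exp$exclusivity)
      expect_equal(row$n_missing, exp$n_missing)
    }
  }
})

ranking_fixture <- function() {
  # 4 animals, 3 sites engineered: two PERFECT ns-sites with scores 10 and 6,
  # one synonymous site with the maximal score
  m <- matrix(c(
    "HOM_ALT", "HOM_ALT", "HOM_REF", "HOM_REF", # chr1:10, score 10
    "HET", "HET", "HOM_REF", "HOM_REF",         # chr1:20, score 6
    "HOM_ALT", "HOM_ALT", "HOM_REF", "HOM_REF"  # chr1:30, synonymous, score 10
  ), nrow = 4, dimnames = list(sprintf("A%02d", 1:4), NULL))
  g <- geno_from_matrix(m)
  ann <- tibble::tibble(
    site_id = c("chr1:10", "chr1:20", "chr1:30"),
    gene = c("g1", "g2", "g3"),
    transcript_id = c("t1", "t2", "t3"),
    cds_pos = 1L, protein_pos = c(4L, 9L, 2L),
    codon_ref = "CGG", codon_alt = "CTG",
    ref_aa = c("R", "K", "L"), alt_aa = c("L", "T", "L"),
    effect = c("NONSYNONYMOUS", "NONSYNONYMOUS", "SYNONYMOUS")
  )
  list(g = g, ann = ann,
       gr = grouping_of("c", c("A01", "A02"), c("A03", "A04")))
}

test_that("ranking prefers exclusivity then score and filters synonymous sites", {
  fx <- ranking_fixture()
  res <- segregate(fx$g, fx$gr)
  cand <- rank_candidates(res, fx$ann)
  expect_equal(cand$site_id, c("chr1:10", "chr1:20"))
  expect_equal(cand$rank, c(1L, 2L))
  expect_false("chr1:30" %in% cand$site_id) # synonymous despite top score
  expect_equal(cand$aa_change[1], "R4L")
  expect_error(rank_candidates(res, fx$ann[-1, ]), "unannotated")
})

test_that("exclusive_only mode drops non-exclusive sites", {
  fx <- ranking_fixture()
  g2 <- fx$g
  g2$gt[g2$site_id == "chr1:20" & g2$animal_id == "A04"] <- "HET"
  res <- segregate(g2, fx$gr)
  both <- rank_candidates(res, fx$ann)
  expect_equal(nrow(both), 2)
  only <- rank_candidates(res, fx$ann, mode = "exclusive_only")
  expect_equal(only$site_id, "chr1:10")
})

test_that("sites with excessive missingness are dropped from candidates", {
  fx <- ranking_fixture()
  g2 <- fx$g
  g2$gt[g2$site_id == "chr1:20" & g2$animal_id %in% c("A03", "A04")] <- "MISSING"
  res <- segregate(g2, fx$gr)
  cand <- rank_candidates(res, fx$ann) # 2/4 grouped missing > 20%
  expect_false("chr1:20" %in% cand$site_id)
  kept <- rank_candidates(res, fx$ann, max_missing_frac = 0.5)
  expect_true("chr1:20" %in% kept$site_id)
})

test_that("ties break lexicographically so rankings are reproducible", {
  m <- matrix(rep(c("HOM_ALT", "HOM_ALT", "HOM_REF", "HOM_REF"), 2),
              nrow = 4, dimnames = list(sprintf("A%02d", 1:4), NULL))
  g <- geno_from_matrix(m)
  ann <- tibble::tibble(
    site_id = c("chr1:10", "chr1:20"), gene = c("gA", "gB"),
    transcript_id = c("t1", "t2"), cds_pos = 1L, protein_pos = 1L,
    codon_ref = "CGG", codon_alt = "CTG", ref_aa = "R", alt_aa = "L",
    effect = "NONSYNONYMOUS"
  )
  res <- segregate(g, grouping_of("c", c("A01", "A02"), c("A03", "A04")))
  cand <- rank_candidates(res, ann)
  expect_equal(cand$site_id, c("chr1:10", "chr1:20"))
})

test_that("screen objects expose tidy, glance and plot methods", {
  fx <- ranking_fixture()
  sc <- screen_candidates(fx$g, fx$gr, fx$ann)
  expect_s3_class(sc, "mhag_screen")
  expect_equal(nrow(tidy(sc)), 2)
  gl <- glance(sc)
  expect_equal(gl$n_clones, 1L)
  expect_equal(gl$n_sites, 3L)
  expect_equal(gl$top_score, 10L)
  expect_s3_class(autoplot(sc), "ggplot")
})
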