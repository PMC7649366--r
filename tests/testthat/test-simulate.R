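small_params <- function(...) {
  defaults <- list(n_animals = 10, n_sites = 60, n_clones = 6, n_genes = 10,
                   gene_codons = 40, seed = 33)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

test_that("cohort generation is deterministic in the seed and only the seed", {
  a <- simulate_reactivity(generate_cohort(small_params()))
  b <- simulate_reactivity(generate_cohort(small_params()))
  expect_equal(a$genotypes, b$genotypes)
  expect_equal(a$truth, b$truth)
  expect_equal(a$reactivity, b$reactivity)
  expect_equal(a$proteome$cds, b$proteome$cds)

  c <- simulate_reactivity(generate_cohort(small_params(seed = 34)))
  expect_false(identical(a$genotypes$gt, c$genotypes$gt))
  expect_false(identical(a$reactivity$sfc, c$reactivity$sfc))
})

test_that("simulation parameters are echoed in the planted truth", {
  b <- generate_cohort(simulation_params(
    n_animals = 21, n_sites = 40, n_clones = 4, n_genes = 6,
    gene_codons = 40, carriers_per_clone = 2, seed = 35
  ))
  expect_equal(nrow(b$truth), 4)
  expect_true(all(lengths(b$truth$carriers) == 2))
  expect_equal(dplyr::n_distinct(b$genotypes$animal_id), 21)
  expect_equal(dplyr::n_distinct(b$genotypes$site_id), 40)
  # distinct patterns by construction
  keys <- vapply(b$truth$carriers, paste, "", collapse = ";")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("infeasible parameters are rejected up front", {
  expect_error(simulation_params(n_animals = 4, carriers_per_clone = 4),
               "non-empty negative group")
  expect_error(simulation_params(n_sites = 10, n_clones = 20), "n_sites")
  expect_error(simulation_params(genotyping_error_rate = 1.2), "rates")
  expect_error(simulation_params(n_clones = 20, n_genes = 10), "one gene per clone")
})

test_that("zero-error cohorts plant PERFECT maximal-score causal sites", {
  b <- generate_cohort(small_params())
  res <- segregate(b$genotypes, truth_groupings(b))
  for (i in seq_len(nrow(b$truth))) {
    row <- res[res$clone_id == b$truth$clone_id[i] &
                 res$site_id == b$truth$site_id[i], ]
    expect_equal(row$exclusivity, "PERFECT")
    expect_equal(row$score, 5L * length(b$truth$carriers[[i]]))
  }
})

test_that("HET planting exercises the 3-point path", {
  b <- generate_cohort(small_params(carrier_genotype = "HET"))
  res <- segregate(b$genotypes, truth_groupings(b))
  row <- res[res$clone_id == b$truth$clone_id[1] &
               res$site_id == b$truth$site_id[1], ]
  expect_equal(row$score, 3L * length(b$truth$carriers[[1]]))
  expect_equal(row$exclusivity, "PERFECT")
})

test_that("genotype corruption is identity at rate 0 and total at missing rate 1", {
  g <- random_genotype_tbl(8, 10, seed = 36, p_missing = 0)
  expect_equal(corrupt_genotypes(g, 0, 0), g)
  all_miss <- corrupt_genotypes(g, 0, 1)
  expect_true(all(all_miss$gt == "MISSING"))
})

test_that("the corrupted-call fraction concentrates around the error rate", {
  g <- random_genotype_tbl(50, 200, seed = 37, p_missing = 0) # 10,000 calls
  rate <- 0.05
  corrupted <- corrupt_genotypes(g, rate, 0, seed = 38)
  frac <- mean(corrupted$gt != g$gt)
  sd3 <- 3 * sqrt(rate * (1 - rate) / nrow(g))
  expect_lt(abs(frac - rate), sd3)
})

test_that("zero-noise reactivity binarizes back to the exact carrier sets", {
  b <- simulate_reactivity(generate_cohort(small_params()))
  gr <- derive_groupings(b$reactivity)
  for (i in seq_len(nrow(b$truth))) {
    j <- match(b$truth$clone_id[i], gr$clone_id)
    expect_equal(gr$pos_animals[[j]], b$truth$carriers[[i]])
  }
})

test_that("a ten-target panel yields the two-positive binary pattern", {
  b <- simulate_reactivity(generate_cohort(
    simulation_params(n_animals = 21, n_sites = 30, n_clones = 5, n_genes = 8,
                      gene_codons = 40, carriers_per_clone = 2,
                      targets_per_clone = 10, seed = 39)
  ))
  called <- call_reactivity(b$reactivity)
  per_clone <- dplyr::count(called, clone_id, positive)
  pos_counts <- dplyr::filter(per_clone, positive)$n
  expect_equal(pos_counts, rep(2L, 5))
  expect_equal(dplyr::count(called, clone_id)$n, rep(10L, 5))
  # targets always include the carriers
  for (i in 1:5) {
    tgts <- called$target_id[called$clone_id == b$truth$clone_id[i]]
    expect_true(all(b$truth$carriers[[i]] %in% tgts))
  }
})

test_that("saturating well noise decouples groupings from the truth", {
  b <- simulate_reactivity(generate_cohort(
    small_params(false_positive_rate = 0.5, false_negative_rate = 0.5)
  ))
  gr <- suppressWarnings(derive_groupings(b$reactivity))
  agree <- vapply(seq_len(nrow(b$truth)), function(i) {
    j <- match(b$truth$clone_id[i], gr$clone_id)
    identical(gr$pos_animals[[j]], b$truth$carriers[[i]])
  }, logical(1))
  expect_false(all(agree))
})

test_that("shared-pattern mode can replant identical carrier sets", {
  p <- small_params(n_animals = 4, carriers_per_clone = 2, n_clones = 10,
                    distinct_patterns = FALSE)
  b <- generate_cohort(p)
  keys <- vapply(b$truth$carriers, paste, "", collapse = ";")
  expect_true(anyDuplicated(keys) > 0) # 10 clones over C(4,2)=6 patterns
  rep <- pattern_report(truth_groupings(b))
  expect_lt(dplyr::n_distinct(rep$pattern_id), 10)
})

test_that("cohort bundles round-trip through their on-disk formats", {
  b <- simulate_reactivity(generate_cohort(small_params()))
  dir <- tempfile()
  paths <- write_cohort(b, dir)
  g <- read_vcf(paths$vcf)
  expect_equal(
    dplyr::arrange(g[, c("animal_id", "site_id", "gt")], site_id, animal_id),
    dplyr::arrange(b$genotypes[, c("animal_id", "site_id", "gt")],
                   site_id, animal_id)
  )
  prot <- read_proteome(paths$fasta, paths$transcripts)
  expect_equal(prot$cds, b$proteome$cds)
  react <- read_reactivity(paths$reactivity)
  expect_equal(nrow(react), nrow(b$reactivity))
})
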