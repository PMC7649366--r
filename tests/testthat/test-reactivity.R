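write_reactivity_text <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("reactivity TSVs parse into validated long tables", {
  tf <- write_reactivity_text(c(
    "clone_id\tcy01\tcy02\tbackground",
    "T01\t150\t4\t5"
  ))
  r <- read_reactivity(tf)
  expect_equal(nrow(r), 2)
  expect_equal(r$sfc[match(c("cy01", "cy02"), r$target_id)], c(150, 4))
  expect_equal(unique(r$background_mean), 5)
  expect_equal(unique(r$background_sd), 0)
})

test_that("bad reactivity tables are rejected", {
  nonnum <- write_reactivity_text(c("clone_id\tcy01\tbackground",
                                    "T01\thigh\t5"))
  expect_error(read_reactivity(nonnum), "numeric")
  neg <- write_reactivity_text(c("clone_id\tcy01\tbackground",
                                 "T01\t-3\t5"))
  expect_error(read_reactivity(neg), "non-negative")
  empty <- write_reactivity_text("clone_id\tbackground")
  expect_error(read_reactivity(empty), "empty table")
  ragged <- write_reactivity_text(c("clone_id\tcy01\tcy02\tbackground",
                                    "T01\t5\t5"))
  suppressWarnings(expect_error(read_reactivity(ragged), "malformed"))
})

test_that("reactivity round-trips through TSV", {
  tf <- write_reactivity_text(c(
    "clone_id\tcy01\tcy02\tcy03\tbackground\tbackground_sd",
    "T01\t150\t4\t220\t5\t2.5",
    "T02\t3\t180\t2\t6\t1.5"
  ))
  r <- read_reactivity(tf)
  tf2 <- tempfile(fileext = ".tsv")
  write_reactivity(r, tf2)
  expect_equal(read_reactivity(tf2), r)
})

test_that("well positivity follows the max of fold, SD and floor thresholds", {
  expect_true(call_well(150, background_mean = 5, background_sd = 2))
  expect_false(call_well(40, background_mean = 40, background_sd = 2))
  expect_false(call_well(0, background_mean = 0))
  # floor dominates a tiny background
  expect_false(call_well(19, background_mean = 1, background_sd = 0))
  expect_true(call_well(20, background_mean = 1, background_sd = 0))
  # SD criterion dominates a wide background
  expect_false(call_well(100, 30, 30, positivity_params(fold_over_background = 2)))
})

test_that("raising any positivity threshold never flips a negative positive", {
  set.seed(42)
  for (i in 1:200) {
    sfc <- runif(1, 0, 300)
    bg <- runif(1, 0, 40)
    sd <- runif(1, 0, 15)
    base <- positivity_params()
    before <- call_well(sfc, bg, sd, base)
    for (bump in list(
      positivity_params(fold_over_background = base$fold_over_background * 2),
      positivity_params(sd_multiplier = base$sd_multiplier * 2),
      positivity_params(absolute_floor = base$absolute_floor * 2)
    )) {
      after <- call_well(sfc, bg, sd, bump)
      expect_false(!before && after)
    }
  }
})

make_react <- function() {
  tibble::tibble(
    clone_id = "T11",
    target_id = sprintf("cy%02d", 1:10),
    sfc = c(250, 180, rep(3, 8)),
    background_mean = 5, background_sd = 2
  )
}

test_that("groupings split targets into positive and negative sets", {
  gr <- derive_groupings(make_react())
  expect_equal(gr$pos_animals[[1]], c("cy01", "cy02"))
  expect_equal(length(gr$neg_animals[[1]]), 8)
  expect_true(gr$mappable)
})

test_that("clones without contrast are flagged unmappable", {
  r <- make_react()
  r$sfc <- 0
  expect_warning(gr <- derive_groupings(r), "unmappable")
  expect_false(gr$mappable)
  expect_equal(gr$pos_animals[[1]], character(0))

  r$sfc <- 500
  expect_warning(gr2 <- derive_groupings(r), "unmappable")
  expect_false(gr2$mappable)
  expect_equal(gr2$neg_animals[[1]], character(0))
  expect_error(derive_groupings(make_react(), clone_ids = "nope"),
               "unknown clone")
})

test_that("groupings are invariant under row permutation of the table", {
  r <- dplyr::bind_rows(
    make_react(),
    dplyr::mutate(make_react(), clone_id = "T12", sfc = rev(sfc))
  )
  set.seed(1)
  shuffled <- r[sample(nrow(r)), ]
  a <- derive_groupings(r)
  b <- derive_groupings(shuffled, clone_ids = a$clone_id)
  expect_equal(a, b)
})

test_that("pattern report partitions clones by identical positive sets", {
  gr <- dplyr::bind_rows(
    grouping_of("c1", c("A", "B"), c("C")),
    grouping_of("c2", c("A", "B"), c("C")),
    grouping_of("c3", c("C"), c("A", "B"))
  )
  rep <- pattern_report(gr)
  expect_equal(dplyr::n_distinct(rep$pattern_id), 2)
  expect_equal(rep$n_clones_with_pattern[rep$clone_id %in% c("c1", "c2")],
               c(2, 2))
  single <- pattern_report(grouping_of("only", "A", "B"))
  expect_equal(dplyr::n_distinct(single$pattern_id), 1)
})

test_that("groupings round-trip through their TSV representation", {
  gr <- dplyr::bind_rows(
    grouping_of("c1", c("A", "B"), c("C", "D")),
    grouping_of("c2", character(0), c("A", "B", "C", "D"))
  )
  tf <- tempfile(fileext = ".tsv")
  write_groupings(gr, tf)
  back <- read_groupings(tf)
  expect_equal(back$pos_animals, gr$pos_animals)
  expect_equal(back$neg_animals, gr$neg_animals)
  expect_equal(back$mappable, gr$mappable)
})
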