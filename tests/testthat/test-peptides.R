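random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

test_that("interior variants tile into three variant-spanning 15-mers", {
  set.seed(7)
  prot <- random_protein(100)
  tiles <- tile_variant_15mers(prot, 50)
  expect_equal(nrow(tiles), 3)
  expect_equal(tiles$start, c(39L, 43L, 47L))
  expect_true(all(!is.na(tiles$variant_offset)))
  expect_true(all(tiles$length == 15))
  expect_equal(tiles$sequence, substr(rep(prot, 3), tiles$start, tiles$end))
})

test_that("terminal clipping keeps coverage for variants near protein ends", {
  set.seed(8)
  p23 <- random_protein(23)
  near <- tile_variant_15mers(p23, 12) # window is the whole protein
  expect_equal(nrow(near), 3)
  expect_equal(range(near$start), c(1L, 9L))

  p100 <- random_protein(100)
  clipped <- tile_variant_15mers(p100, 3) # window 1-14, shorter than 15
  expect_equal(nrow(clipped), 1)
  expect_equal(clipped$length, 14L)
  expect_equal(clipped$variant_offset, 3L)
  expect_error(tile_variant_15mers(p100, 0), "outside protein")
  expect_error(tile_variant_15mers(p100, 101), "outside protein")
})

test_that("tiled peptides are exact substrings and interior tilings span the variant", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(30:200, 1)
    v <- sample(seq_len(n), 1)
    prot <- random_protein(n)
    tiles <- tile_variant_15mers(prot, v)
    expect_equal(tiles$sequence,
                 substr(rep(prot, nrow(tiles)), tiles$start, tiles$end))
    if (v > 11 && v <= n - 11) {
      expect_equal(nrow(tiles), 3)
      expect_true(all(!is.na(tiles$variant_offset)))
    }
    spans <- !is.na(tiles$variant_offset)
    expect_equal(substr(tiles$sequence[spans], tiles$variant_offset[spans],
                        tiles$variant_offset[spans]),
                 rep(substr(prot, v, v), sum(spans)))
  }
})

test_that("stimulatory peptide intersection yields the shared 11-mer window", {
  set.seed(10)
  prot <- random_protein(80)
  tiles <- tile_variant_15mers(prot, 50)
  shared <- intersect_stimulatory(tiles[1, ], tiles[2, ])
  expect_equal(shared$length, 11L)
  expect_equal(shared$start, 43L)
  expect_equal(shared$sequence, substr(prot, 43, 53))
  # idempotence and disjointness
  expect_equal(intersect_stimulatory(tiles[1, ], tiles[1, ])$sequence,
               tiles$sequence[1])
  expect_error(intersect_stimulatory(tiles[1, ],
                                     tile_variant_15mers(prot, 70)[3, ]),
               "do not overlap")
})

test_that("k-mer ladders enumerate every window substring", {
  set.seed(11)
  w11 <- random_protein(11)
  ladder <- enumerate_kmers(w11)
  expect_equal(nrow(ladder), 10) # 4 + 3 + 2 + 1
  expect_setequal(ladder$sequence, oracle_all_kmers(w11, 8, 11))
  expect_equal(nrow(enumerate_kmers(w11, k_min = 11, k_max = 11)), 1)
  expect_equal(nrow(enumerate_kmers(random_protein(8))), 1)
  expect_error(enumerate_kmers(""), "empty window")

  for (i in 1:20) {
    n <- sample(5:25, 1)
    k1 <- sample(3:10, 1)
    k2 <- k1 + sample(0:4, 1)
    w <- random_protein(n)
    expected <- sum(pmax(0, n - seq(k1, k2) + 1))
    if (expected == 0) {
      expect_error(enumerate_kmers(w, k1, k2))
    } else {
      got <- enumerate_kmers(w, k1, k2)
      expect_equal(nrow(got), expected)
      expect_setequal(got$sequence, oracle_all_kmers(w, k1, k2))
    }
  }
})

test_that("wild-type controls revert the variant residue and are involutive", {
  prot <- paste0(strrep("A", 42), "L", strrep("G", 40)) # variant L at 43
  tiles <- tile_variant_15mers(prot, 43)
  p <- tiles[2, ]
  wt <- wildtype_control(p, "R")
  expect_equal(substr(wt$sequence, p$variant_offset, p$variant_offset), "R")
  expect_true(is.na(wt$variant_offset))
  expect_equal(wt$name, name_peptide(wt$sequence))
  # back-substitution restores the original sequence
  wt$variant_offset <- p$variant_offset
  back <- wildtype_control(wt, "L")
  expect_equal(back$sequence, p$sequence)
  expect_error(wildtype_control(p, "L"), "already")
  expect_error(wildtype_control(wt |> dplyr::mutate(variant_offset = NA_integer_), "R"),
               "no variant")
})

test_that("peptide names are first residue + last residue + length", {
  expect_equal(name_peptide("SPNKAGLDIW"), "SW10")
  expect_equal(name_peptide("LPNKAGLDIQW"), "LW11")
  expect_equal(name_peptide("A"), "AA1")
  expect_error(name_peptide(""), "empty")
})

test_that("the Mafa-A1*063 motif demands its four anchors and 8-11mer length", {
  m <- mafa_a1_063_motif()
  res <- motif_match(c("SPNKAGLDIW", "LPNKAGLDIW", "SPNKAGLDIA"), m)
  expect_equal(res$motif_match, c(TRUE, FALSE, FALSE))
  expect_false(res$anchor_1[2])
  expect_false(res$anchor_cterm[3])
  # length bounds
  long <- motif_match("SPNKAGLDIDIW", m) # 12-mer
  expect_false(long$motif_match)
  short <- motif_match("SPNKAGW", m) # 7-mer
  expect_false(short$motif_match)
})

test_that("motif matching ignores residues at non-anchor positions", {
  set.seed(12)
  m <- mafa_a1_063_motif()
  for (i in 1:50) {
    len <- sample(8:11, 1)
    mid <- random_protein(len - 4)
    pep <- paste0("SPN", mid, "W")
    expect_true(motif_match(pep, m)$motif_match)
  }
})

test_that("motif specs load from the packaged YAML config", {
  cfg <- system.file("extdata", "motifs.yaml", package = "mhagmap")
  motifs <- read_motifs(cfg)
  expect_true("Mafa-A1*063" %in% names(motifs))
  got <- motifs[["Mafa-A1*063"]]
  ref <- mafa_a1_063_motif()
  expect_equal(got$anchors, ref$anchors)
  expect_equal(got$cterm, ref$cterm)
  expect_equal(got$length_range, ref$length_range)
})
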