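#' Name a peptide from its sequence
#'
#' Field convention: first residue letter + last residue letter + length,
#' e.g. a 10-mer starting with serine and ending with tryptophan is "SW10".
#'
#' @param sequence Amino-acid string(s).
#' @return Character vector of names.
#' @export
#' @examples
#' name_peptide("SPNKAGLDIW") # "SW10"
name_peptide <- function(sequence) {
  assert_that(all(nchar(sequence) > 0), "cannot name an empty peptide")
  paste0(substr(sequence, 1, 1),
         substr(sequence, nchar(sequence), nchar(sequence)),
         nchar(sequence))
}

new_peptide_set <- function(sequence, start, variant_offset = NA_integer_) {
  tibble::tibble(
    name = name_peptide(sequence),
    sequence = sequence,
    start = as.integer(start),
    end = as.integer(start + nchar(sequence) - 1L),
    length = nchar(sequence),
    variant_offset = as.integer(variant_offset)
  )
}

#' Variant-centered overlapping peptide tiling
#'
#' Reproduces the screening design for candidate antigens: take the `flank`
#' residues upstream and downstream of the variant residue (default 11 each
#' side), clip that window to the protein, and tile it with peptides of
#' `length` (default 15) overlapping by `overlap` residues (default 11, i.e.
#' a step of 4). If stepping undershoots the window end, a final
#' end-anchored peptide completes the coverage; if the clipped window is
#' shorter than `length`, the whole window is emitted as a single peptide.
#' For an interior variant the defaults yield exactly three 15-mers, all
#' spanning the variant residue.
#'
#' @param protein Amino-acid sequence (the variant-carrying protein).
#' @param variant_pos 1-based residue index of the variant.
#' @param flank Residues kept on each side of the variant.
#' @param length Peptide length.
#' @param overlap Overlap between successive peptides (must be < `length`).
#' @return A peptide tibble: `name`, `sequence`, `start`, `end`, `length`,
#'   `variant_offset` (position of the variant within the peptide, `NA` if
#'   not spanned).
#' @export
tile_variant_15mers <- function(protein, variant_pos, flank = 11,
                                length = 15, overlap = 11) {
  n <- nchar(protein)
  assert_that(variant_pos >= 1 && variant_pos <= n,
              sprintf("variant position %d outside protein (1..%d)", variant_pos, n))
  assert_that(flank >= 0, "flank must be >= 0")
  assert_that(overlap < length, "overlap must be smaller than peptide length")
  win_start <- max(1L, as.integer(variant_pos - flank))
  win_end <- min(n, as.integer(variant_pos + flank))
  win_len <- win_end - win_start + 1L

  if (win_len < length) {
    starts <- win_start
    lens <- win_len
  } else {
    step <- as.integer(length - overlap)
    starts <- seq.int(win_start, win_end - length + 1L, by = step)
    if (starts[base::length(starts)] + length - 1L < win_end) {
      starts <- c(starts, win_end - length + 1L) # end-anchored completion
    }
    lens <- rep(as.integer(length), base::length(starts))
  }
  seqs <- substr(rep(protein, base::length(starts)), starts, starts + lens - 1L)
  offs <- ifelse(variant_pos >= starts & variant_pos <= starts + lens - 1L,
                 variant_pos - starts + 1L, NA_integer_)
  new_peptide_set(seqs, starts, offs)
}

#' Shared window of two overlapping peptides from the same protein
#'
#' The fine-mapping step: the epitope recognised via two stimulatory
#' peptides must lie in their intersection. For adjacent 15-mers tiled at
#' step 4 the shared region is an 11-mer.
#'
#' @param a,b Single-row peptide tibbles (or rows of one) from the same
#'   protein, with overlapping coordinates.
#' @return A one-row peptide tibble for the shared window; the variant
#'   offset is recomputed when both inputs span the variant.
#' @export
intersect_stimulatory <- function(a, b) {
  assert_that(nrow(a) == 1 && nrow(b) == 1, "expected single-row peptides")
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  assert_that(s <= e, sprintf("peptides %s (%d-%d) and %s (%d-%d) do not overlap",
                              a$name, a$start, a$end, b$name, b$start, b$end))
  from_a <- substr(a$sequence, s - a$start + 1L, e - a$start + 1L)
  from_b <- substr(b$sequence, s - b$start + 1L, e - b$start + 1L)
  assert_that(identical(from_a, from_b),
              "peptides disagree on their shared window; not from the same protein?")
  var_pos <- if (!is.na(a$variant_offset)) a$start + a$variant_offset - 1L else NA
  off <- if (!is.na(var_pos) && var_pos >= s && var_pos <= e) {
    var_pos - s + 1L
  } else {
    NA_integer_
  }
  new_peptide_set(from_a, s, off)
}

#' Enumerate all k-mers of a window for minimal-epitope mapping
#'
#' All contiguous k-mers, for each k in `k_min..k_max`, that fit in the
#' window; the count is the closed form sum over k of max(0, |window|-k+1).
#' Used to build the truncation ladder (8- to 11-mers by default) from
#' which the minimal optimal epitope is identified.
#'
#' @param window A one-row peptide tibble (e.g. from
#'   [intersect_stimulatory()]) or a plain amino-acid string.
#' @param k_min,k_max Inclusive k-mer length range (defaults 8 and 11).
#' @return A peptide tibble, coordinates relative to the source protein
#'   when `window` carries them (1-based within the window otherwise).
#' @export
enumerate_kmers <- function(window, k_min = 8, k_max = 11) {
  if (is.character(window)) {
    assert_that(length(window) == 1 && nchar(window) > 0, "empty window")
    window <- new_peptide_set(window, 1L)
  }
  assert_that(nrow(window) == 1, "expected a single window")
  w <- window$sequence
  assert_that(nchar(w) > 0, "empty window")
  assert_that(k_min >= 1 && k_min <= k_max, "need 1 <= k_min <= k_max")
  var_pos <- if (!is.na(window$variant_offset)) {
    window$start + window$variant_offset - 1L
  } else {
    NA_integer_
  }
  rows <- purrr::map(seq.int(k_min, k_max), function(k) {
    n_k <- nchar(w) - k + 1L
    if (n_k < 1L) return(NULL)
    starts <- window$start + seq_len(n_k) - 1L
    seqs <- substr(rep(w, n_k), seq_len(n_k), seq_len(n_k) + k - 1L)
    offs <- ifelse(!is.na(var_pos) & var_pos >= starts & var_pos <= starts + k - 1L,
                   var_pos - starts + 1L, NA_integer_)
    new_peptide_set(seqs, starts, offs)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  assert_that(nrow(out) > 0,
              sprintf("window of %d aa holds no k-mer in %d..%d",
                      nchar(w), k_min, k_max))
  out
}

#' Wild-type control peptide for a variant-spanning peptide
#'
#' Replaces the variant residue with the reference residue, clearing the
#' variant offset and renaming — the control design used to show that only
#' the variant peptide is stimulatory.
#'
#' @param peptide A one-row peptide tibble with a `variant_offset`.
#' @param ref_aa Reference residue (single letter); must differ from the
#'   residue currently at the variant offset.
#' @return A one-row peptide tibble.
#' @export
wildtype_control <- function(peptide, ref_aa) {
  assert_that(nrow(peptide) == 1, "expected a single peptide")
  assert_that(!is.na(peptide$variant_offset),
              "peptide has no variant residue to revert")
  cur <- substr(peptide$sequence, peptide$variant_offset, peptide$variant_offset)
  assert_that(!identical(cur, ref_aa),
              sprintf("residue at variant offset is already %s", ref_aa))
  s <- peptide$sequence
  substr(s, peptide$variant_offset, peptide$variant_offset) <- ref_aa
  new_peptide_set(s, peptide$start)
}

#' MHC class I anchor-residue motif specification
#'
#' @param anchors Named list mapping 1-based peptide positions to allowed
#'   residue sets (character vectors).
#' @param cterm Allowed residues at the carboxy terminus.
#' @param length_range Length 2 integer vector, inclusive min/max peptide
#'   length.
#' @param allele Optional allele label.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(anchors, cterm, length_range = c(8L, 11L),
                       allele = NA_character_) {
  pos <- as.integer(names(anchors))
  assert_that(!anyNA(pos) && all(pos >= 1) && all(pos <= length_range[1]),
              "anchor positions must lie within the minimum peptide length")
  structure(list(anchors = anchors, cterm = cterm,
                 length_range = as.integer(length_range), allele = allele),
            class = "motif_spec")
}

#' The Mafa-A1*063 peptide-binding motif
#'
#' Anchor residues: serine at position 1, proline at position 2, asparagine
#' at position 3, tryptophan at the carboxy terminus; peptide lengths 8-11.
#'
#' @return A `motif_spec` object.
#' @export
mafa_a1_063_motif <- function() {
  motif_spec(anchors = list(`1` = "S", `2` = "P", `3` = "N"),
             cterm = "W", length_range = c(8L, 11L),
             allele = "Mafa-A1*063")
}

#' Read motif specifications from a YAML config
#'
#' The config maps allele names to `anchors` (position -> residues),
#' `cterm`, and `length_range`. A config with the built-in Mafa-A1*063
#' entry ships at `system.file("extdata", "motifs.yaml", package = "mhagmap")`.
#'
#' @param path YAML file path.
#' @return Named list of `motif_spec` objects.
#' @export
read_motifs <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(spec, allele) {
    motif_spec(anchors = purrr::map(spec$anchors, as.character),
               cterm = as.character(spec$cterm),
               length_range = as.integer(spec$length_range),
               allele = allele)
  })
}

#' Test peptides against an MHC-I anchor motif
#'
#' A peptide matches when its length is inside the motif's range, every
#' anchor position carries an allowed residue, and the C-terminal residue
#' is allowed. Non-anchor positions are unconstrained.
#'
#' @param peptides A peptide tibble (or character vector of sequences).
#' @param motif A `motif_spec` object (default [mafa_a1_063_motif()]).
#' @return The peptide tibble with one logical column per anchor
#'   (`anchor_1`, ..., `anchor_cterm`), `length_ok`, and the overall
#'   `motif_match`.
#' @export
#' @examples
#' motif_match(c("SPNKAGLDIW", "LPNKAGLDIW"))$motif_match # TRUE FALSE
motif_match <- function(peptides, motif = mafa_a1_063_motif()) {
  if (is.character(peptides)) {
    peptides <- new_peptide_set(peptides, 1L)
  }
  seqs <- peptides$sequence
  out <- peptides
  out$length_ok <- nchar(seqs) >= motif$length_range[1] &
    nchar(seqs) <= motif$length_range[2]
  ok <- out$length_ok
  for (p in names(motif$anchors)) {
    pi <- as.integer(p)
    hit <- substr(seqs, pi, pi) %in% motif$anchors[[p]] & nchar(seqs) >= pi
    out[[paste0("anchor_", p)]] <- hit
    ok <- ok & hit
  }
  cterm_hit <- substr(seqs, nchar(seqs), nchar(seqs)) %in% motif$cterm
  out$anchor_cterm <- cterm_hit
  out$motif_match <- ok & cterm_hit
  out
}

#' Write a peptide set as FASTA and/or TSV
#'
#' FASTA record ids are `name|start-end` so naming collisions stay
#' distinguishable by coordinates.
#'
#' @param peptides A peptide tibble.
#' @param fasta_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the peptide tibble.
#' @export
write_peptides <- function(peptides, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    aa <- Biostrings::AAStringSet(peptides$sequence)
    names(aa) <- paste0(peptides$name, "|", peptides$start, "-", peptides$end)
    Biostrings::writeXStringSet(aa, fasta_path)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(peptides, tsv_path, progress = FALSE)
  }
  invisible(peptides)
}
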