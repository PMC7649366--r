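#' Classify variant sites as synonymous / non-synonymous on a proteome model
#'
#' For every site x overlapping-transcript pair, locates the affected codon
#' from the CDS coordinate map, substitutes the alternate allele (alleles
#' are reverse-complemented first for minus-strand transcripts), translates
#' both codons with the standard genetic code, and classifies the effect:
#' `SYNONYMOUS` (same residue), `NONSYNONYMOUS` (different residue),
#' `NONSENSE` (alternate codon is a stop), or `NON_CODING` (the site falls
#' outside every CDS — reported as a record, not an error).
#'
#' @param proteome A `proteome` object ([read_proteome()]).
#' @param sites A tibble with at least `site_id`, `chrom`, `pos`, `ref`,
#'   `alt` — e.g. [site_table()] of a genotype tibble.
#' @return A tibble with one row per site x transcript (plus one
#'   `NON_CODING` row per unmapped site): `site_id`, `gene`,
#'   `transcript_id`, `cds_pos`, `protein_pos`, `codon_ref`, `codon_alt`,
#'   `ref_aa`, `alt_aa`, `effect`.
#' @export
#' @examples
#' prot <- new_proteome(
#'   c(tx1 = "ATGCGGTGG"),
#'   tibble::tibble(transcript_id = "tx1", gene = "g1", chrom = "chr1",
#'                  strand = "+", exons = list(tibble::tibble(start = 1, end = 9)))
#' )
#' sites <- tibble::tibble(site_id = "chr1:5", chrom = "chr1", pos = 5L,
#'                         ref = "G", alt = "T")
#' annotate_variants(prot, sites) # CGG -> CTG, R -> L
annotate_variants <- function(proteome, sites) {
  need <- c("site_id", "chrom", "pos", "ref", "alt")
  assert_that(all(need %in% names(sites)),
              sprintf("sites table lacks columns: %s",
                      paste(setdiff(need, names(sites)), collapse = ", ")))
  hits <- genomic_to_cds(proteome, sites$chrom, sites$pos)

  non_coding <- setdiff(seq_len(nrow(sites)), unique(hits$query))
  nc_rows <- tibble::tibble(
    site_id = sites$site_id[non_coding],
    gene = NA_character_, transcript_id = NA_character_,
    cds_pos = NA_integer_, protein_pos = NA_integer_,
    codon_ref = NA_character_, codon_alt = NA_character_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    effect = rep("NON_CODING", length(non_coding))
  )
  if (nrow(hits) == 0) return(nc_rows)

  q <- hits$query
  minus <- hits$strand == "-"
  ref_cds <- ifelse(minus, comp_base(sites$ref[q]), sites$ref[q])
  alt_cds <- ifelse(minus, comp_base(sites$alt[q]), sites$alt[q])

  codon_idx <- (hits$cds_pos - 1L) %/% 3L
  pos_in_codon <- (hits$cds_pos - 1L) %% 3L + 1L
  codon_ref <- substr(proteome$cds[hits$transcript_id],
                      codon_idx * 3L + 1L, codon_idx * 3L + 3L)

  cds_base <- substr(codon_ref, pos_in_codon, pos_in_codon)
  bad <- cds_base != ref_cds
  if (any(bad)) {
    b <- which(bad)[1]
    rlang::abort(sprintf(
      "reference mismatch at %s on %s: VCF ref %s, CDS base %s",
      sites$site_id[q[b]], hits$transcript_id[b], sites$ref[q[b]], cds_base[b]
    ))
  }
  codon_alt <- codon_ref
  substr(codon_alt, pos_in_codon, pos_in_codon) <- alt_cds

  ref_aa <- unname(Biostrings::GENETIC_CODE[codon_ref])
  alt_aa <- unname(Biostrings::GENETIC_CODE[codon_alt])
  effect <- dplyr::case_when(
    alt_aa == "*" & ref_aa != "*" ~ "NONSENSE",
    ref_aa == alt_aa ~ "SYNONYMOUS",
    TRUE ~ "NONSYNONYMOUS"
  )
  coding <- tibble::tibble(
    site_id = sites$site_id[q],
    gene = hits$gene,
    transcript_id = hits$transcript_id,
    cds_pos = hits$cds_pos,
    protein_pos = codon_idx + 1L,
    codon_ref = codon_ref, codon_alt = codon_alt,
    ref_aa = ref_aa, alt_aa = alt_aa, effect = effect
  )
  dplyr::bind_rows(coding, nc_rows) |>
    dplyr::arrange(match(.data$site_id, sites$site_id))
}

#' Reference protein with one annotated substitution applied
#'
#' @param proteome A `proteome` object.
#' @param record A single-row annotation tibble (from [annotate_variants()])
#'   with effect `NONSYNONYMOUS`.
#' @return The protein sequence carrying the alternate residue; it differs
#'   from the reference protein at exactly `protein_pos`.
#' @export
protein_with_variant <- function(proteome, record) {
  assert_that(nrow(record) == 1, "record must be a single annotation row")
  assert_that(identical(record$effect, "NONSYNONYMOUS"),
              sprintf("variant protein requires a NONSYNONYMOUS record, got %s",
                      record$effect))
  prot <- translate_cds(proteome, record$transcript_id)
  assert_that(record$protein_pos >= 1 && record$protein_pos <= nchar(prot),
              "protein_pos outside translated protein")
  substr(prot, record$protein_pos, record$protein_pos) <- record$alt_aa
  prot
}

#' Append the annotation dialect to a genotype tibble's site metadata
#'
#' Joins the most severe per-site annotation (`NONSENSE` >
#' `NONSYNONYMOUS` > `SYNONYMOUS` > `NON_CODING`, ties broken by
#' transcript id) onto the genotype calls, so that written VCFs carry
#' `GENE`/`TRID`/`CDSPOS` INFO keys.
#'
#' @param genotypes A genotype-calls tibble.
#' @param annotations Output of [annotate_variants()].
#' @return The genotype tibble with `gene`, `transcript_id`, `cds_pos`,
#'   `effect` columns (replacing any existing ones).
#' @export
join_annotations <- function(genotypes, annotations) {
  severity <- c(NONSENSE = 1, NONSYNONYMOUS = 2, SYNONYMOUS = 3, NON_CODING = 4)
  best <- annotations |>
    dplyr::arrange(severity[.data$effect], .data$transcript_id) |>
    dplyr::distinct(.data$site_id, .keep_all = TRUE) |>
    dplyr::select("site_id", "gene", "transcript_id", "cds_pos", "effect")
  genotypes |>
    dplyr::select(-dplyr::any_of(c("gene", "transcript_id", "cds_pos", "effect"))) |>
    dplyr::left_join(best, by = "site_id")
}
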