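#' Read a CDS FASTA plus transcript coordinate table into a proteome model
#'
#' The FASTA holds one coding sequence (CDS, DNA, coding orientation) per
#' transcript. The transcript table is a TSV with columns `transcript_id`,
#' `gene`, `chrom`, `strand` (`+`/`-`), and `exons`: comma-separated 1-based
#' inclusive genomic intervals `start-end`, listed in ascending genomic
#' order. For minus-strand transcripts CDS position 1 corresponds to the
#' highest genomic coordinate of the last exon interval.
#'
#' @param fasta_path CDS FASTA path.
#' @param transcript_table_path Transcript table TSV path.
#' @return A `proteome` object: list with `cds` (named character vector of
#'   CDS sequences) and `tx` (transcript tibble with an `exons` list-column
#'   of `start`/`end` tibbles).
#' @export
read_proteome <- function(fasta_path, transcript_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cds <- toupper(as.character(seqs))
  names(cds) <- sub("\\s.*$", "", names(seqs))
  tx <- readr::read_tsv(transcript_table_path, show_col_types = FALSE,
                        progress = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exons")
  assert_that(all(need %in% names(tx)),
              sprintf("transcript table lacks columns: %s",
                      paste(setdiff(need, names(tx)), collapse = ", ")))
  if (!"gene" %in% names(tx)) tx$gene <- tx$transcript_id
  tx$exons <- purrr::map(tx$exons, parse_exons)
  new_proteome(cds, tx)
}

parse_exons <- function(spec) {
  iv <- strsplit(spec, ",", fixed = TRUE)[[1]]
  m <- stringr::str_match(iv, "^(\\d+)-(\\d+)$")
  assert_that(!anyNA(m[, 1]), sprintf("malformed exon interval spec: %s", spec))
  tibble::tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
}

#' Construct a proteome model from in-memory components
#'
#' @param cds Named character vector of CDS sequences (coding orientation).
#' @param tx Transcript tibble with `transcript_id`, `gene`, `chrom`,
#'   `strand` and an `exons` list-column of `start`/`end` tibbles.
#' @return A validated `proteome` object.
#' @export
new_proteome <- function(cds, tx) {
  assert_that(all(tx$strand %in% c("+", "-")), "strand must be '+' or '-'")
  missing_seq <- setdiff(tx$transcript_id, names(cds))
  assert_that(length(missing_seq) == 0,
              sprintf("transcript id(s) missing from FASTA: %s",
                      paste(missing_seq, collapse = ", ")))
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    len <- sum(tx$exons[[i]]$end - tx$exons[[i]]$start + 1L)
    assert_that(all(tx$exons[[i]]$end >= tx$exons[[i]]$start),
                sprintf("transcript %s has an inverted exon interval", id))
    assert_that(len == nchar(cds[[id]]),
                sprintf("transcript %s: exon span (%d) != CDS length (%d)",
                        id, len, nchar(cds[[id]])))
    assert_that(len %% 3L == 0L,
                sprintf("transcript %s: CDS length %d not divisible by 3", id, len))
  }
  out <- structure(list(cds = cds[tx$transcript_id], tx = tx),
                   class = "proteome")
  out$.exon_index <- exon_index(out)
  out
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %d transcripts, %s nt of CDS\n",
              nrow(x$tx), format(sum(nchar(x$cds)), big.mark = ",")))
  invisible(x)
}

#' Write the proteome model to disk (CDS FASTA + transcript table TSV)
#'
#' @param proteome A `proteome` object.
#' @param fasta_path,transcript_table_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_proteome <- function(proteome, fasta_path, transcript_table_path) {
  seqs <- Biostrings::DNAStringSet(proteome$cds)
  Biostrings::writeXStringSet(seqs, fasta_path)
  flat <- proteome$tx |>
    dplyr::mutate(exons = purrr::map_chr(.data$exons, function(e) {
      paste(paste0(e$start, "-", e$end), collapse = ",")
    }))
  readr::write_tsv(flat[, c("transcript_id", "gene", "chrom", "strand", "exons")],
                   transcript_table_path, progress = FALSE)
  invisible(fasta_path)
}

#' Map genomic coordinates to CDS coordinates
#'
#' Vectorised lookup from `(chrom, pos)` pairs to per-transcript 1-based CDS
#' positions. Positions that fall outside every CDS yield no rows; callers
#' treat those as non-coding.
#'
#' @param proteome A `proteome` object.
#' @param chrom,pos Equal-length vectors of sequence names and 1-based
#'   genomic positions.
#' @return A tibble with `query` (input index), `transcript_id`, `gene`,
#'   `strand`, `cds_pos`. A query spanning several overlapping transcripts
#'   contributes one row per transcript.
#' @export
genomic_to_cds <- function(proteome, chrom, pos) {
  assert_that(length(chrom) == length(pos), "chrom and pos lengths differ")
  ex <- exon_index(proteome)
  out <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    hit <- which(chrom == ex$chrom[i] & pos >= ex$start[i] & pos <= ex$end[i])
    if (length(hit) == 0) next
    cds_pos <- if (ex$strand[i] == "+") {
      ex$cds_offset[i] + (pos[hit] - ex$start[i]) + 1L
    } else {
      ex$cds_offset[i] + (ex$end[i] - pos[hit]) + 1L
    }
    out[[i]] <- tibble::tibble(
      query = hit, transcript_id = ex$transcript_id[i], gene = ex$gene[i],
      strand = ex$strand[i], cds_pos = cds_pos
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(query = integer(), transcript_id = character(),
                          gene = character(), strand = character(),
                          cds_pos = integer()))
  }
  dplyr::arrange(res, .data$query, .data$transcript_id)
}

# flat exon table with per-exon CDS offsets; memoised per proteome identity
exon_index <- function(proteome) {
  cached <- proteome$.exon_index
  if (!is.null(cached)) return(cached)
  rows <- purrr::map(seq_len(nrow(proteome$tx)), function(i) {
    tx <- proteome$tx[i, ]
    e <- tx$exons[[1]]
    widths <- e$end - e$start + 1L
    # CDS reading order: ascending genomic for "+", descending for "-"
    ord <- if (tx$strand == "+") seq_len(nrow(e)) else rev(seq_len(nrow(e)))
    offsets <- integer(nrow(e))
    offsets[ord] <- cumsum(c(0L, widths[ord]))[seq_len(nrow(e))]
    tibble::tibble(
      transcript_id = tx$transcript_id, gene = tx$gene, chrom = tx$chrom,
      strand = tx$strand, start = e$start, end = e$end, cds_offset = offsets
    )
  })
  dplyr::bind_rows(rows)
}

# map CDS positions back to genomic positions (inverse of genomic_to_cds)
cds_to_genomic <- function(proteome, transcript_id, cds_pos) {
  ex <- exon_index(proteome)
  ex_split <- split(ex, ex$transcript_id)
  vapply(seq_along(transcript_id), function(k) {
    e <- ex_split[[transcript_id[k]]]
    within <- cds_pos[k] - e$cds_offset
    i <- which(within >= 1L & within <= (e$end - e$start + 1L))[1]
    if (is.na(i)) rlang::abort(sprintf("CDS position %d outside transcript %s",
                                       cds_pos[k], transcript_id[k]))
    if (e$strand[i] == "+") e$start[i] + within[i] - 1L else e$end[i] - within[i] + 1L
  }, integer(1))
}

#' Translate a transcript's CDS to protein
#'
#' Standard (vertebrate nuclear) genetic code; a trailing stop codon is
#' dropped, internal stops are kept as `*` so callers can detect them.
#'
#' @param proteome A `proteome` object.
#' @param transcript_id Transcript to translate.
#' @return Single-letter amino-acid string.
#' @export
translate_cds <- function(proteome, transcript_id) {
  assert_that(transcript_id %in% names(proteome$cds),
              sprintf("unknown transcript: %s", transcript_id))
  aa <- translate_dna(proteome$cds[[transcript_id]])
  sub("\\*$", "", aa)
}

translate_dna <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}
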