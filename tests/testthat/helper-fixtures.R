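# In-code fixture builders shared across the suite.

# genotype-calls tibble from an animals x sites character matrix
geno_from_matrix <- function(m, chrom = "chr1", ref = "G", alt = "T") {
  animals <- rownames(m) %||% sprintf("A%02d", seq_len(nrow(m)))
  pos <- seq_len(ncol(m)) * 10L
  tibble::tibble(
    animal_id = rep(animals, times = ncol(m)),
    site_id = rep(paste0(chrom, ":", pos), each = nrow(m)),
    chrom = chrom,
    pos = rep(pos, each = nrow(m)),
    ref = ref, alt = alt,
    gt = as.vector(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genotype_tbl <- function(n_animals, n_sites, seed,
                                p_missing = 0.1) {
  set.seed(seed)
  m <- matrix(
    sample(c("HOM_REF", "HET", "HOM_ALT", "MISSING"),
           n_animals * n_sites, replace = TRUE,
           prob = c(0.5, 0.2, 0.2, p_missing) / (0.9 + p_missing)),
    nrow = n_animals,
    dimnames = list(sprintf("A%02d", seq_len(n_animals)), NULL)
  )
  geno_from_matrix(m)
}

# single-transcript proteome on a bare chromosome
simple_proteome <- function(cds, strand = "+", start = 101L,
                            id = "tx1", gene = "g1", chrom = "chr1") {
  new_proteome(
    stats::setNames(cds, id),
    tibble::tibble(
      transcript_id = id, gene = gene, chrom = chrom, strand = strand,
      exons = list(tibble::tibble(start = as.integer(start),
                                  end = as.integer(start + nchar(cds) - 1L)))
    )
  )
}

# grouping tibble built directly from positive/negative id sets
grouping_of <- function(clone_id, pos, neg) {
  tibble::tibble(clone_id = clone_id,
                 pos_animals = list(sort(pos)), neg_animals = list(sort(neg)),
                 mappable = length(pos) > 0 && length(neg) > 0)
}

# groupings equal to a bundle's planted carrier sets (whole-panel contrast)
truth_groupings <- function(bundle) {
  animals <- sort(unique(bundle$genotypes$animal_id))
  tibble::tibble(
    clone_id = bundle$truth$clone_id,
    pos_animals = bundle$truth$carriers,
    neg_animals = purrr::map(bundle$truth$carriers, ~ setdiff(animals, .x)),
    mappable = TRUE
  )
}
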