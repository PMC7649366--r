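#' Parameters for synthetic mHAg-discovery cohorts
#'
#' Defaults emulate the mapping study design: a panel of 21 MHC-identical
#' animals, 69 alloreactive T cell clones each recognising one planted
#' causal non-synonymous SNP carried by 2 animals, an exome-scale background
#' of common biallelic SNPs, and strongly separated ELISpot counts
#' (background wells around 5 SFC, positive wells around 200 SFC,
#' negative-binomially overdispersed). Error, missingness and well-noise
#' rates default to zero; they are the dials for robustness experiments.
#'
#' @param n_animals Cohort size (default 21).
#' @param n_sites Total variant sites, causal included (default 5000; a
#'   down-scaled exome).
#' @param n_clones Number of T cell clones, one planted causal ns-SNP each
#'   (default 69).
#' @param n_genes Number of transcripts; defaults to `n_clones + 30` so
#'   every clone gets its own causal gene.
#' @param gene_codons Codons per synthetic CDS (default 120).
#' @param carriers_per_clone Animals carrying each causal allele: a single
#'   count (default 2, the canonical two-of-the-panel reactivity pattern)
#'   or a length-2 inclusive range sampled per clone.
#' @param distinct_patterns Plant a distinct carrier set per clone (default
#'   `TRUE`, keeping each clone's truth unambiguous); `FALSE` allows
#'   repeated patterns, e.g. to exercise duplicate-pattern reporting.
#' @param carrier_genotype `"HOM_ALT"` (default; makes the maximum
#'   segregation score exact) or `"HET"`.
#' @param targets_per_clone Targets typed per clone; `NULL` (default) types
#'   the whole panel, a smaller number draws the carriers plus random
#'   non-carriers (e.g. 10 for a ten-target panel).
#' @param background_maf_range Uniform range for background-site allele
#'   frequencies (default `c(0.25, 0.5)`: common post-bottleneck
#'   polymorphisms).
#' @param genotyping_error_rate,missing_rate Per-call corruption
#'   probabilities (defaults 0).
#' @param background_sfc_mean,positive_sfc_mean Mean SFC counts for
#'   non-carrier and carrier wells (defaults 5 and 200).
#' @param sfc_dispersion Negative-binomial size parameter for well counts
#'   (default 30; smaller = more overdispersed).
#' @param false_positive_rate,false_negative_rate Probability that a
#'   non-carrier/carrier well draws from the wrong count distribution
#'   (defaults 0).
#' @param seed Integer seed; every stochastic output is a deterministic
#'   function of the parameters and this seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_animals = 21,
                              n_sites = 5000,
                              n_clones = 69,
                              n_genes = NULL,
                              gene_codons = 120,
                              carriers_per_clone = 2,
                              distinct_patterns = TRUE,
                              carrier_genotype = c("HOM_ALT", "HET"),
                              targets_per_clone = NULL,
                              background_maf_range = c(0.25, 0.5),
                              genotyping_error_rate = 0,
                              missing_rate = 0,
                              background_sfc_mean = 5,
                              positive_sfc_mean = 200,
                              sfc_dispersion = 30,
                              false_positive_rate = 0,
                              false_negative_rate = 0,
                              seed = 1L) {
  carrier_genotype <- match.arg(carrier_genotype)
  n_genes <- n_genes %||% (n_clones + 30L)
  p <- list(
    n_animals = as.integer(n_animals), n_sites = as.integer(n_sites),
    n_clones = as.integer(n_clones), n_genes = as.integer(n_genes),
    gene_codons = as.integer(gene_codons),
    carriers_per_clone = as.integer(carriers_per_clone),
    distinct_patterns = isTRUE(distinct_patterns),
    carrier_genotype = carrier_genotype,
    targets_per_clone = if (is.null(targets_per_clone)) NULL
                        else as.integer(targets_per_clone),
    background_maf_range = background_maf_range,
    genotyping_error_rate = genotyping_error_rate,
    missing_rate = missing_rate,
    background_sfc_mean = background_sfc_mean,
    positive_sfc_mean = positive_sfc_mean,
    sfc_dispersion = sfc_dispersion,
    false_positive_rate = false_positive_rate,
    false_negative_rate = false_negative_rate,
    seed = as.integer(seed)
  )
  rates <- c(p$genotyping_error_rate, p$missing_rate,
             p$false_positive_rate, p$false_negative_rate)
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  assert_that(p$background_sfc_mean >= 0 && p$positive_sfc_mean >= 0 &&
                p$sfc_dispersion > 0, "count parameters must be non-negative")
  assert_that(p$n_sites >= p$n_clones, "need n_sites >= n_clones")
  assert_that(p$n_genes >= p$n_clones,
              "need one gene per clone: n_genes >= n_clones")
  assert_that(length(p$carriers_per_clone) %in% c(1L, 2L) &&
                all(p$carriers_per_clone >= 1) &&
                max(p$carriers_per_clone) < p$n_animals &&
                !is.unsorted(p$carriers_per_clone),
              "carriers_per_clone must be a count or increasing range leaving a non-empty negative group")
  if (!is.null(p$targets_per_clone)) {
    assert_that(p$targets_per_clone > max(p$carriers_per_clone) &&
                  p$targets_per_clone <= p$n_animals,
                "targets_per_clone must exceed carriers_per_clone and fit the cohort")
  }
  assert_that(p$gene_codons >= 30, "genes must be at least 30 codons")
  structure(p, class = "simulation_params")
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate a ground-truthed synthetic discovery cohort
#'
#' Builds every input the discovery pipeline consumes, with known truth:
#' a synthetic proteome (single-exon CDS transcripts laid alternately on
#' the plus and minus strand of one chromosome), a genotype matrix over
#' `n_sites` coding SNPs, and a truth table. Each clone gets one causal
#' non-synonymous SNP in its own gene whose alternate allele is given
#' (`HOM_ALT` by default) to exactly its carrier set; every other animal is
#' homozygous reference there. Background sites draw Hardy-Weinberg
#' genotypes at common allele frequencies. Genotyping error and missingness
#' are then applied at the configured rates via [corrupt_genotypes()].
#'
#' With zero error and missingness, every truth-table site is
#' `PERFECT`-exclusive for its clone's carrier set and annotates to its
#' planted amino-acid change.
#'
#' @param params A [simulation_params()] object.
#' @return A `cohort_bundle`: list with `genotypes`, `proteome`,
#'   `annotations` (all sites), `truth` (one row per clone: `clone_id`,
#'   `site_id`, `gene`, `transcript_id`, `carriers` list-column,
#'   `protein_pos`, `ref_aa`, `alt_aa`), `reactivity` (filled by
#'   [simulate_reactivity()]), and `params`.
#' @export
generate_cohort <- function(params = simulation_params()) {
  p <- params
  set.seed(p$seed)
  animals <- sprintf("MCM%03d", seq_len(p$n_animals))
  clone_ids <- sprintf("T%02d", seq_len(p$n_clones))

  proteome <- random_proteome(p)
  ex <- exon_index(proteome)
  cds_len <- p$gene_codons * 3L

  # one causal ns-SNP per clone, each in its own gene, interior codon so
  # the default 15-mer tiling window never clips
  causal_tx <- proteome$tx$transcript_id[seq_len(p$n_clones)]
  causal <- purrr::map(seq_len(p$n_clones), function(i) {
    plant_nonsynonymous(proteome, causal_tx[i], p)
  }) |> dplyr::bind_rows()
  causal$clone_id <- clone_ids

  # background sites at distinct CDS positions anywhere in the proteome
  n_bg <- p$n_sites - p$n_clones
  all_slots <- tibble::tibble(
    transcript_id = rep(proteome$tx$transcript_id, each = cds_len),
    cds_pos = rep(seq_len(cds_len), times = p$n_genes)
  )
  taken <- paste(causal$transcript_id, causal$cds_pos)
  free <- which(!(paste(all_slots$transcript_id, all_slots$cds_pos) %in% taken))
  assert_that(length(free) >= n_bg,
              "proteome too small for n_sites; raise n_genes or gene_codons")
  bg_slots <- all_slots[sort(sample(free, n_bg)), ]
  bg <- random_background_sites(proteome, bg_slots)

  sites <- dplyr::bind_rows(
    dplyr::mutate(causal, is_causal = TRUE),
    dplyr::mutate(bg, is_causal = FALSE)
  ) |>
    dplyr::arrange(.data$pos) |>
    dplyr::mutate(site_id = paste0(.data$chrom, ":", .data$pos))
  assert_that(!anyDuplicated(sites$site_id), "site position collision")

  # genotype matrix: animals x sites classes
  gt <- matrix("HOM_REF", nrow = p$n_animals, ncol = nrow(sites),
               dimnames = list(animals, sites$site_id))
  bg_idx <- which(!sites$is_causal)
  maf <- stats::runif(length(bg_idx), p$background_maf_range[1],
                      p$background_maf_range[2])
  for (k in seq_along(bg_idx)) {
    q <- maf[k]
    gt[, bg_idx[k]] <- sample(
      c("HOM_REF", "HET", "HOM_ALT"), p$n_animals, replace = TRUE,
      prob = c((1 - q)^2, 2 * q * (1 - q), q^2)
    )
  }
  carriers <- draw_carrier_sets(animals, p)
  causal_idx <- match(causal$site_id_key, paste(sites$transcript_id, sites$cds_pos))
  for (i in seq_len(p$n_clones)) {
    gt[, causal_idx[i]] <- "HOM_REF"
    gt[carriers[[i]], causal_idx[i]] <- p$carrier_genotype
  }

  genotypes <- tibble::tibble(
    animal_id = rep(animals, times = nrow(sites)),
    site_id = rep(sites$site_id, each = p$n_animals),
    chrom = rep(sites$chrom, each = p$n_animals),
    pos = rep(sites$pos, each = p$n_animals),
    ref = rep(sites$ref, each = p$n_animals),
    alt = rep(sites$alt, each = p$n_animals),
    gt = as.vector(gt) # column-major: animals vary fastest, matching the reps
  )
  if (p$genotyping_error_rate > 0 || p$missing_rate > 0) {
    genotypes <- corrupt_genotypes(genotypes, p$genotyping_error_rate,
                                   p$missing_rate)
  }

  annotations <- annotate_variants(
    proteome,
    dplyr::select(sites, "site_id", "chrom", "pos", "ref", "alt")
  )
  truth <- tibble::tibble(
    clone_id = clone_ids,
    site_id = sites$site_id[causal_idx],
    gene = causal$gene,
    transcript_id = causal$transcript_id,
    carriers = carriers,
    protein_pos = causal$protein_pos,
    ref_aa = causal$ref_aa,
    alt_aa = causal$alt_aa
  )
  structure(
    list(genotypes = validate_genotypes(genotypes), proteome = proteome,
         annotations = annotations, truth = truth, reactivity = NULL,
         params = p),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d animals x %d sites, %d clones (seed %d)%s\n",
    x$params$n_animals, dplyr::n_distinct(x$genotypes$site_id),
    nrow(x$truth), x$params$seed,
    if (is.null(x$reactivity)) "" else ", reactivity simulated"
  ))
  invisible(x)
}

# synthetic proteome: n_genes single-exon CDS laid along one chromosome,
# alternating strand, 100 bp intergenic gaps, no internal stop codons
random_proteome <- function(p) {
  cds_len <- p$gene_codons * 3L
  codons <- sense_codons()
  ids <- sprintf("TX%03d", seq_len(p$n_genes))
  genes <- sprintf("GENE%03d", seq_len(p$n_genes))
  starts <- 101L + (seq_len(p$n_genes) - 1L) * (cds_len + 100L)
  strands <- rep(c("+", "-"), length.out = p$n_genes)
  cds <- vapply(seq_len(p$n_genes), function(i) {
    paste(sample(codons, p$gene_codons, replace = TRUE), collapse = "")
  }, character(1))
  names(cds) <- ids
  tx <- tibble::tibble(
    transcript_id = ids, gene = genes, chrom = "chr1", strand = strands,
    exons = purrr::map(starts, function(s) {
      tibble::tibble(start = s, end = s + cds_len - 1L)
    })
  )
  new_proteome(cds, tx)
}

# pick an interior codon and a substitution that is non-synonymous and
# non-stop; returns the genomic-site row plus planted truth fields
plant_nonsynonymous <- function(proteome, transcript_id, p) {
  tx <- proteome$tx[proteome$tx$transcript_id == transcript_id, ]
  cds <- proteome$cds[[transcript_id]]
  gc <- Biostrings::GENETIC_CODE
  repeat {
    codon_i <- sample(12:(p$gene_codons - 12L), 1)
    pos_in_codon <- sample(1:3, 1)
    codon <- substr(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    ref_base <- substr(codon, pos_in_codon, pos_in_codon)
    alt_base <- sample(setdiff(DNA_BASES, ref_base), 1)
    codon_alt <- codon
    substr(codon_alt, pos_in_codon, pos_in_codon) <- alt_base
    ref_aa <- unname(gc[codon])
    alt_aa <- unname(gc[codon_alt])
    if (ref_aa != alt_aa && alt_aa != "*" && ref_aa != "*") break
  }
  cds_pos <- (codon_i - 1L) * 3L + pos_in_codon
  gpos <- cds_to_genomic(proteome, transcript_id, cds_pos)
  minus <- tx$strand == "-"
  tibble::tibble(
    chrom = tx$chrom, pos = gpos,
    ref = if (minus) comp_base(ref_base) else ref_base,
    alt = if (minus) comp_base(alt_base) else alt_base,
    gene = tx$gene, transcript_id = transcript_id, cds_pos = cds_pos,
    protein_pos = codon_i, ref_aa = ref_aa, alt_aa = alt_aa,
    site_id_key = paste(transcript_id, cds_pos)
  )
}

# carrier sets per clone; distinct patterns by default so every clone's
# truth is unambiguous (two clones sharing a carrier set would see each
# other's causal site as an equally perfect candidate)
draw_carrier_sets <- function(animals, p) {
  sizes <- if (length(p$carriers_per_clone) == 2) {
    sample(seq.int(p$carriers_per_clone[1], p$carriers_per_clone[2]),
           p$n_clones, replace = TRUE)
  } else {
    rep(p$carriers_per_clone, p$n_clones)
  }
  carriers <- vector("list", p$n_clones)
  seen <- character(0)
  attempts <- 0L
  for (i in seq_len(p$n_clones)) {
    repeat {
      cand <- sort(sample(animals, sizes[i]))
      key <- paste(cand, collapse = ";")
      if (!p$distinct_patterns || !(key %in% seen)) break
      attempts <- attempts + 1L
      assert_that(attempts < 1000L * p$n_clones,
                  "cannot plant distinct reactivity patterns; fewer clones or more animals needed")
    }
    seen <- c(seen, key)
    carriers[[i]] <- cand
  }
  carriers
}

# vectorised construction of background coding SNPs at given CDS slots
random_background_sites <- function(proteome, slots) {
  tx <- proteome$tx[match(slots$transcript_id, proteome$tx$transcript_id), ]
  cds_base <- substr(proteome$cds[slots$transcript_id],
                     slots$cds_pos, slots$cds_pos)
  # uniformly one of the three other bases
  others <- matrix(DNA_BASES[t(vapply(cds_base, function(b)
    which(DNA_BASES != b), integer(3)))], ncol = 3)
  alt_cds <- others[cbind(seq_len(nrow(slots)),
                          sample.int(3, nrow(slots), replace = TRUE))]
  gpos <- cds_to_genomic(proteome, slots$transcript_id, slots$cds_pos)
  minus <- tx$strand == "-"
  tibble::tibble(
    chrom = tx$chrom, pos = gpos,
    ref = ifelse(minus, comp_base(cds_base), cds_base),
    alt = ifelse(minus, comp_base(alt_cds), alt_cds),
    gene = tx$gene, transcript_id = slots$transcript_id,
    cds_pos = slots$cds_pos,
    protein_pos = NA_integer_, ref_aa = NA_character_, alt_aa = NA_character_,
    site_id_key = paste(slots$transcript_id, slots$cds_pos)
  )
}

#' Apply genotyping error and missingness to a genotype tibble
#'
#' Each call is independently replaced by a uniformly chosen *different*
#' genotype class with probability `error_rate`, then set to `MISSING` with
#' probability `missing_rate`.
#'
#' @param genotypes A genotype-calls tibble.
#' @param error_rate,missing_rate Per-call probabilities in `[0, 1]`.
#' @param seed Optional seed; by default corruption continues the caller's
#'   RNG stream.
#' @return The corrupted genotype tibble.
#' @export
corrupt_genotypes <- function(genotypes, error_rate, missing_rate, seed = NULL) {
  assert_that(error_rate >= 0 && error_rate <= 1 &&
                missing_rate >= 0 && missing_rate <= 1,
              "rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  gt <- genotypes$gt
  n <- length(gt)
  if (error_rate > 0) {
    flip <- stats::runif(n) < error_rate & gt != "MISSING"
    classes <- c("HOM_REF", "HET", "HOM_ALT")
    # uniformly one of the two other genotype classes
    pick <- function(cur) sample(setdiff(classes, cur), 1)
    gt[flip] <- vapply(gt[flip], pick, character(1))
  }
  if (missing_rate > 0) {
    gt[stats::runif(n) < missing_rate] <- "MISSING"
  }
  genotypes$gt <- gt
  genotypes
}

#' Simulate ELISpot reactivity tables for a cohort bundle
#'
#' For each clone, draws per-well spot counts: wells whose target animal
#' carries the clone's causal allele draw from a negative binomial around
#' `positive_sfc_mean`, non-carrier wells around `background_sfc_mean`
#' (both with size `sfc_dispersion`; ELISpot replicates are overdispersed
#' relative to Poisson). False-positive / false-negative wells swap the
#' drawing distribution at the configured rates. When `targets_per_clone`
#' is smaller than the panel, the target set is the clone's carriers plus
#' random non-carriers.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param params Defaults to the bundle's own parameters.
#' @return The bundle with a long `reactivity` tibble attached
#'   (`clone_id`, `target_id`, `sfc`, `background_mean`, `background_sd`).
#' @export
simulate_reactivity <- function(bundle, params = bundle$params) {
  p <- params
  set.seed(p$seed + 1L)
  animals <- sort(unique(bundle$genotypes$animal_id))
  bg_sd <- sqrt(p$background_sfc_mean +
                  p$background_sfc_mean^2 / p$sfc_dispersion)
  tabs <- purrr::map(seq_len(nrow(bundle$truth)), function(i) {
    carriers <- bundle$truth$carriers[[i]]
    targets <- if (is.null(p$targets_per_clone) ||
                   p$targets_per_clone >= length(animals)) {
      animals
    } else {
      sort(c(carriers, sample(setdiff(animals, carriers),
                              p$targets_per_clone - length(carriers))))
    }
    is_carrier <- targets %in% carriers
    hot <- is_carrier
    if (p$false_negative_rate > 0) {
      hot[is_carrier] <- stats::runif(sum(is_carrier)) >= p$false_negative_rate
    }
    if (p$false_positive_rate > 0) {
      fp <- stats::runif(sum(!is_carrier)) < p$false_positive_rate
      hot[!is_carrier] <- fp
    }
    mu <- ifelse(hot, p$positive_sfc_mean, p$background_sfc_mean)
    tibble::tibble(
      clone_id = bundle$truth$clone_id[i],
      target_id = targets,
      sfc = stats::rnbinom(length(targets), size = p$sfc_dispersion, mu = mu),
      background_mean = p$background_sfc_mean,
      background_sd = bg_sd
    )
  })
  bundle$reactivity <- dplyr::bind_rows(tabs)
  bundle
}

#' Score a candidate screen against a bundle's planted truth
#'
#' A clone's causal variant counts as *recovered* when the clone's rank-1
#' candidate is the planted site, classified `PERFECT`, with the exact
#' expected segregation score (5 points per carrier planted `HOM_ALT`,
#' 3 per `HET` carrier). The three components are also reported
#' separately, so partial degradation under genotyping error is visible.
#'
#' @param screen A `mhag_screen` over groupings matching the bundle's truth
#'   carrier sets.
#' @param bundle The `cohort_bundle` the screen was run on.
#' @return A tibble with one row per clone (`rank1_correct`, `perfect`,
#'   `score_exact`, `recovered`) carrying the overall `recovery_rate` as an
#'   attribute.
#' @export
evaluate_recovery <- function(screen, bundle) {
  per_carrier <- if (bundle$params$carrier_genotype == "HOM_ALT") 5L else 3L
  top <- dplyr::filter(screen$candidates, .data$rank == 1)
  out <- bundle$truth |>
    dplyr::transmute(
      .data$clone_id, causal_site = .data$site_id,
      expected_score = per_carrier * lengths(.data$carriers)
    ) |>
    dplyr::left_join(
      dplyr::select(top, "clone_id", top_site = "site_id", "score",
                    "exclusivity"),
      by = "clone_id"
    ) |>
    dplyr::mutate(
      rank1_correct = !is.na(.data$top_site) &
        .data$top_site == .data$causal_site,
      perfect = .data$rank1_correct & .data$exclusivity == "PERFECT",
      score_exact = .data$rank1_correct & .data$score == .data$expected_score,
      recovered = .data$rank1_correct & .data$perfect & .data$score_exact
    )
  attr(out, "recovery_rate") <- mean(out$recovered)
  out
}

#' Write every on-disk artifact of a cohort bundle
#'
#' Emits exactly the formats the readers consume: `cohort.vcf`,
#' `proteome.fasta`, `transcripts.tsv`, `reactivity.tsv` (when simulated)
#' and `truth.tsv` (carriers ";"-joined).
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    fasta = file.path(dir, "proteome.fasta"),
    transcripts = file.path(dir, "transcripts.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(bundle$genotypes, paths$vcf)
  write_proteome(bundle$proteome, paths$fasta, paths$transcripts)
  truth_flat <- bundle$truth |>
    dplyr::mutate(carriers = purrr::map_chr(.data$carriers, paste, collapse = ";"))
  readr::write_tsv(truth_flat, paths$truth, progress = FALSE)
  if (!is.null(bundle$reactivity)) {
    paths$reactivity <- file.path(dir, "reactivity.tsv")
    write_reactivity(bundle$reactivity, paths$reactivity)
  }
  invisible(paths)
}

#' The 68-animal APOBEC3C frequency panel, rebuilt from its published counts
#'
#' A deterministic fixture generator for the cohort in which the
#' SW10-encoding SNP's prevalence was measured: 68 animals typed at
#' `NC_027902.1:80990325`, 63 homozygous reference, four heterozygous for
#' the G>T allele (leucine variant) and one heterozygous for the G>A allele
#' (glutamine variant). Decomposed into the two biallelic columns
#' `NC_027902.1:80990325:T` and `NC_027902.1:80990325:A`.
#'
#' @return A genotype-calls tibble (136 rows: 68 animals x 2 alt columns).
#' @export
#' @examples
#' carrier_frequency(apobec3c_frequency_panel(), aggregate_alts = TRUE)
apobec3c_frequency_panel <- function() {
  animals <- sprintf("MCM%03d", 1:68)
  gt_t <- rep("HOM_REF", 68)
  gt_t[1:4] <- "HET" # G>T carriers
  gt_a <- rep("HOM_REF", 68)
  gt_a[5] <- "HET" # the single G>A carrier
  base <- tibble::tibble(
    chrom = "NC_027902.1", pos = 80990325L, ref = "G", gene = "APOBEC3C",
    transcript_id = NA_character_, cds_pos = NA_integer_
  )
  dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 68), ], animal_id = animals, alt = "T",
                  site_id = "NC_027902.1:80990325:T", gt = gt_t),
    dplyr::mutate(base[rep(1, 68), ], animal_id = animals, alt = "A",
                  site_id = "NC_027902.1:80990325:A", gt = gt_a)
  ) |>
    dplyr::select("animal_id", "site_id", "chrom", "pos", "ref", "alt", "gt",
                  "gene", "transcript_id", "cds_pos") |>
    validate_genotypes()
}
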