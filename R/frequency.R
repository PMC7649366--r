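#' Cohort carrier and allele frequencies for variant sites
#'
#' Counts genotype classes per site and derives the carrier count (animals
#' with at least one alternate allele), the carrier percentage, and the
#' alternate allele frequency. Animals with `MISSING` calls are excluded
#' from the denominators and reported in `n_missing`.
#'
#' With `aggregate_alts = TRUE`, decomposed multiallelic columns sharing a
#' `chrom:pos` are pooled: an animal carrying *any* alternate allele at the
#' position counts once, alternate copies are summed across alleles, and an
#' animal is `MISSING` only if missing in every sibling column. Pooled rows
#' carry `alt = "*"` and `site_id = "chrom:pos"`.
#'
#' `carrier_pct` is rounded half-up to two decimals (the report scale);
#' `carrier_frac` and `alt_allele_freq` keep full precision.
#'
#' @param genotypes A genotype-calls tibble ([read_vcf()]).
#' @param site_ids Sites to summarise (default: all). With pooling these
#'   may also be bare `"chrom:pos"` prefixes.
#' @param aggregate_alts Pool decomposed alternate-allele columns per
#'   position (default `FALSE`).
#' @return A tibble with one row per site (or pooled position): `site_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `n_animals`, `n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n_missing`, `n_carriers`, `carrier_pct`, `carrier_frac`,
#'   `alt_allele_freq`.
#' @export
#' @examples
#' carrier_frequency(apobec3c_frequency_panel(), aggregate_alts = TRUE)
carrier_frequency <- function(genotypes, site_ids = NULL,
                              aggregate_alts = FALSE) {
  validate_genotypes(genotypes)
  if (aggregate_alts) {
    copies_of <- c(HOM_REF = 0, HET = 1, HOM_ALT = 2, MISSING = NA_real_)
    pooled <- genotypes |>
      dplyr::mutate(copies = copies_of[.data$gt]) |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$animal_id) |>
      dplyr::summarise(
        copies = if (all(is.na(.data$copies))) NA_real_ else
          sum(.data$copies, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        site_id = paste0(.data$chrom, ":", .data$pos),
        alt = "*",
        gt = counts_to_class(pmin(.data$copies, 2))
      )
    tab <- pooled
  } else {
    tab <- genotypes
  }
  if (!is.null(site_ids)) {
    unknown <- setdiff(site_ids, tab$site_id)
    assert_that(length(unknown) == 0,
                sprintf("unknown site id(s): %s", paste(unknown, collapse = ", ")))
    tab <- dplyr::filter(tab, .data$site_id %in% site_ids)
  }
  tab |>
    dplyr::group_by(.data$site_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      n_hom_ref = sum(.data$gt == "HOM_REF"),
      n_het = sum(.data$gt == "HET"),
      n_hom_alt = sum(.data$gt == "HOM_ALT"),
      n_missing = sum(.data$gt == "MISSING"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_carriers = .data$n_het + .data$n_hom_alt,
      n_typed = .data$n_animals - .data$n_missing,
      carrier_frac = ifelse(.data$n_typed > 0, .data$n_carriers / .data$n_typed, NA),
      carrier_pct = round_half_up(100 * .data$carrier_frac, 2),
      alt_allele_freq = ifelse(
        .data$n_typed > 0,
        (.data$n_het + 2 * .data$n_hom_alt) / (2 * .data$n_typed), NA
      )
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
}

#' Write a carrier-frequency report (per-alt plus pooled rows) as TSV
#'
#' @param genotypes A genotype-calls tibble.
#' @param path Output path.
#' @return The combined report tibble, invisibly.
#' @export
write_frequency_report <- function(genotypes, path) {
  per_alt <- carrier_frequency(genotypes, aggregate_alts = FALSE)
  pooled <- carrier_frequency(genotypes, aggregate_alts = TRUE)
  report <- dplyr::bind_rows(per_alt, pooled) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  readr::write_tsv(report, path, progress = FALSE)
  invisible(report)
}
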