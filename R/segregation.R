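#' Points awarded per genotype class in segregation scoring
#'
#' Scoring is relative to the reference genome: 5 points for a homozygous
#' mismatch (`HOM_ALT`), 3 for a heterozygous mismatch (`HET`), 0 for a
#' homozygous match (`HOM_REF`). `MISSING` calls score 0 but are counted
#' separately so fragile candidates are visible (see [segregate()]).
#'
#' @param gt Character vector of genotype classes.
#' @return Integer vector of points.
#' @export
#' @examples
#' genotype_points(c("HOM_ALT", "HET", "HOM_REF", "MISSING")) # 5 3 0 0
genotype_points <- function(gt) {
  assert_that(all(gt %in% GT_CLASSES),
              "genotype calls must be HOM_REF/HET/HOM_ALT/MISSING")
  unname(c(HOM_REF = 0L, HET = 3L, HOM_ALT = 5L, MISSING = 0L)[gt])
}

#' Segregation scores and exclusivity classes for clone groupings
#'
#' For every (variant site, clone grouping) pair, sums genotype points
#' ([genotype_points()]) over the clone's mHAg-positive and mHAg-negative
#' animals; the segregation score is the positive-group sum minus the
#' negative-group sum. Each pair is also classified by allele exclusivity:
#' `EXCLUSIVE` when no negative-group animal carries the alternate allele
#' and at least one positive-group animal does; `PERFECT` when additionally
#' *every* positive-group animal carries it; `NON_EXCLUSIVE` otherwise.
#' `MISSING` calls never count as carrying.
#'
#' Unmappable groupings (empty positive or negative set) are dropped with a
#' warning: the score needs both groups.
#'
#' @param genotypes A genotype-calls tibble ([read_vcf()]).
#' @param groupings A groupings tibble ([derive_groupings()]), or a single
#'   clone's grouping row.
#' @return A tibble with one row per clone x site: `clone_id`, `site_id`,
#'   `pos_points`, `neg_points`, `score`, `exclusivity`, `n_missing` (count
#'   of MISSING calls among the grouped animals), `n_grouped`.
#' @export
segregate <- function(genotypes, groupings) {
  validate_genotypes(genotypes)
  animals_in_matrix <- unique(genotypes$animal_id)
  absent <- setdiff(
    unique(unlist(c(groupings$pos_animals, groupings$neg_animals))),
    animals_in_matrix
  )
  assert_that(length(absent) == 0,
              sprintf("animal(s) in groupings absent from genotype matrix: %s",
                      paste(absent, collapse = ", ")))
  if (!all(groupings$mappable %||% TRUE)) {
    warning(sprintf("dropping %d unmappable clone(s) from segregation",
                    sum(!groupings$mappable)), call. = FALSE)
    groupings <- dplyr::filter(groupings, .data$mappable)
  }
  assert_that(nrow(groupings) > 0, "no mappable groupings to score")

  # animals x sites matrices once; per-clone work is then two colSums
  wide <- genotypes |>
    dplyr::select("animal_id", "site_id", "gt") |>
    tidyr::pivot_wider(names_from = "site_id", values_from = "gt")
  gt_mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(gt_mat) <- wide$animal_id
  pts <- matrix(genotype_points(gt_mat), nrow = nrow(gt_mat),
                dimnames = dimnames(gt_mat))
  carrier <- gt_mat == "HET" | gt_mat == "HOM_ALT"
  miss <- gt_mat == "MISSING"
  site_ids <- colnames(gt_mat)

  per_clone <- purrr::map(seq_len(nrow(groupings)), function(i) {
    pos <- groupings$pos_animals[[i]]
    neg <- groupings$neg_animals[[i]]
    pos_points <- colSums(pts[pos, , drop = FALSE])
    neg_points <- colSums(pts[neg, , drop = FALSE])
    pos_carriers <- colSums(carrier[pos, , drop = FALSE])
    neg_carriers <- colSums(carrier[neg, , drop = FALSE])
    tibble::tibble(
      clone_id = groupings$clone_id[i],
      site_id = site_ids,
      pos_points = as.integer(pos_points),
      neg_points = as.integer(neg_points),
      score = as.integer(pos_points - neg_points),
      exclusivity = dplyr::case_when(
        neg_carriers == 0 & pos_carriers == length(pos) ~ "PERFECT",
        neg_carriers == 0 & pos_carriers >= 1 ~ "EXCLUSIVE",
        TRUE ~ "NON_EXCLUSIVE"
      ),
      n_missing = as.integer(colSums(miss[pos, , drop = FALSE]) +
                               colSums(miss[neg, , drop = FALSE])),
      n_grouped = length(pos) + length(neg)
    )
  })
  dplyr::bind_rows(per_clone)
}

#' Rank non-synonymous candidate sites per clone
#'
#' Filters segregation results to non-synonymous sites and orders them, per
#' clone, by: exclusivity class (`PERFECT` > `EXCLUSIVE` > `NON_EXCLUSIVE`),
#' segregation score (descending), per-gene non-synonymous site count
#' (descending; a proxy for "polymorphic genes"), and finally `site_id`
#' (lexicographic) so the ranking is deterministic. Sites with a missing-call
#' fraction among the grouped animals above `max_missing_frac` are dropped
#' (they score on too little data to trust).
#'
#' @param results A segregation tibble from [segregate()].
#' @param annotations Per-site annotations from [annotate_variants()]; every
#'   scored site must be annotated.
#' @param mode `"default"` keeps all exclusivity classes;
#'   `"exclusive_only"` drops `NON_EXCLUSIVE` sites.
#' @param max_missing_frac Drop sites whose grouped-animal missingness
#'   exceeds this fraction (default 0.2).
#' @return Ranked tibble with annotation columns (`gene`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `aa_change`) and a per-clone `rank`.
#' @export
rank_candidates <- function(results, annotations,
                            mode = c("default", "exclusive_only"),
                            max_missing_frac = 0.2) {
  mode <- match.arg(mode)
  severity <- c(NONSENSE = 1, NONSYNONYMOUS = 2, SYNONYMOUS = 3, NON_CODING = 4)
  best <- annotations |>
    dplyr::arrange(severity[.data$effect], .data$transcript_id) |>
    dplyr::distinct(.data$site_id, .keep_all = TRUE)
  unannotated <- setdiff(unique(results$site_id), best$site_id)
  assert_that(length(unannotated) == 0,
              sprintf("unannotated site(s): %s",
                      paste(utils::head(unannotated, 5), collapse = ", ")))

  gene_ns_counts <- annotations |>
    dplyr::filter(.data$effect == "NONSYNONYMOUS") |>
    dplyr::distinct(.data$gene, .data$site_id) |>
    dplyr::count(.data$gene, name = "gene_ns_count")

  out <- results |>
    dplyr::left_join(
      dplyr::select(best, "site_id", "gene", "transcript_id",
                    "protein_pos", "ref_aa", "alt_aa", "effect"),
      by = "site_id"
    ) |>
    dplyr::filter(.data$effect == "NONSYNONYMOUS") |>
    dplyr::filter(.data$n_missing <= max_missing_frac * .data$n_grouped) |>
    dplyr::left_join(gene_ns_counts, by = "gene") |>
    dplyr::mutate(
      aa_change = paste0(.data$ref_aa, .data$protein_pos, .data$alt_aa),
      excl_rank = match(.data$exclusivity, EXCLUSIVITY_LEVELS)
    )
  if (mode == "exclusive_only") {
    out <- dplyr::filter(out, .data$exclusivity != "NON_EXCLUSIVE")
  }
  out |>
    dplyr::arrange(.data$clone_id, .data$excl_rank, dplyr::desc(.data$score),
                   dplyr::desc(.data$gene_ns_count), .data$site_id) |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-"excl_rank")
}

#' Screen a cohort for candidate mHAg-encoding SNPs
#'
#' One-call wrapper over [segregate()] and [rank_candidates()] that returns
#' a `mhag_screen` object with [generics::tidy()] / [generics::glance()] /
#' [ggplot2::autoplot()] methods.
#'
#' @inheritParams segregate
#' @inheritParams rank_candidates
#' @return An object of class `mhag_screen`: list with `results` (all
#'   scored clone x site pairs), `candidates` (ranked non-synonymous
#'   candidates), `groupings`, and the ranking parameters.
#' @export
screen_candidates <- function(genotypes, groupings, annotations,
                              mode = "default", max_missing_frac = 0.2) {
  results <- segregate(genotypes, groupings)
  candidates <- rank_candidates(results, annotations, mode = mode,
                                max_missing_frac = max_missing_frac)
  structure(
    list(results = results, candidates = candidates, groupings = groupings,
         params = list(mode = mode, max_missing_frac = max_missing_frac)),
    class = "mhag_screen"
  )
}

#' @export
print.mhag_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mhag_screen> %d clone(s) x %d site(s); %d ns-candidates (%d PERFECT, %d EXCLUSIVE)\n",
    g$n_clones, g$n_sites, g$n_candidates, g$n_perfect, g$n_exclusive
  ))
  cat("top candidates:\n")
  print(utils::head(
    dplyr::select(x$candidates, "clone_id", "site_id", "gene", "aa_change",
                  "score", "exclusivity", "rank"), 5))
  invisible(x)
}

#' Tidy the ranked candidate table of a screen
#' @param x A `mhag_screen` object.
#' @param ... Unused.
#' @return The ranked candidates tibble.
#' @export
tidy.mhag_screen <- function(x, ...) x$candidates

#' One-row summary of a screen
#' @param x A `mhag_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: clone/site/candidate counts and exclusivity
#'   class tallies among rank-1 candidates.
#' @export
glance.mhag_screen <- function(x, ...) {
  tibble::tibble(
    n_clones = dplyr::n_distinct(x$results$clone_id),
    n_sites = dplyr::n_distinct(x$results$site_id),
    n_candidates = nrow(x$candidates),
    n_perfect = sum(x$candidates$exclusivity == "PERFECT"),
    n_exclusive = sum(x$candidates$exclusivity == "EXCLUSIVE"),
    top_score = if (nrow(x$candidates)) max(x$candidates$score) else NA_integer_
  )
}

#' Write the ranked candidate table as TSV
#'
#' @param screen A `mhag_screen` object or a ranked candidates tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(screen, path) {
  cand <- if (inherits(screen, "mhag_screen")) screen$candidates else screen
  cols <- c("clone_id", "site_id", "gene", "aa_change", "score",
            "pos_points", "neg_points", "exclusivity", "n_missing", "rank")
  readr::write_tsv(cand[, intersect(cols, names(cand))], path, progress = FALSE)
  invisible(path)
}
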