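#' Default pipeline configuration
#'
#' Configuration is a nested list, readable from YAML ([read_config()]),
#' with precedence overrides > file > defaults. Sections: `inputs` (paths
#' to `vcf`, `proteome_fasta`, `transcript_table`, `reactivity`),
#' `positivity` (see [positivity_params()]), `segregation` (`mode`,
#' `max_missing_frac`), `peptides` (`flank`, `length`, `overlap`, `k_min`,
#' `k_max`), `motif` (`allele`, optional `config` path), `simulate`
#' (see [simulation_params()]), `out_dir`, `seed`.
#'
#' @return The default configuration list.
#' @export
default_config <- function() {
  list(
    inputs = list(vcf = NULL, proteome_fasta = NULL, transcript_table = NULL,
                  reactivity = NULL, groupings = NULL),
    positivity = list(fold_over_background = 3, sd_multiplier = 3,
                      absolute_floor = 20),
    segregation = list(mode = "default", max_missing_frac = 0.2),
    peptides = list(flank = 11, length = 15, overlap = 11, k_min = 8, k_max = 11),
    motif = list(allele = "Mafa-A1*063", config = NULL),
    simulate = list(),
    out_dir = "mhagmap_out",
    seed = 1L
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML config path; `NULL` returns the defaults.
#' @param overrides Named list merged on top (deep merge).
#' @return A configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    assert_that(file.exists(path), sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

merge_config <- function(base, extra) {
  for (k in names(extra)) {
    if (is.list(extra[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], extra[[k]])
    } else {
      base[[k]] <- extra[[k]]
    }
  }
  base
}

config_positivity <- function(config) {
  do.call(positivity_params, config$positivity)
}

require_input <- function(config, field) {
  path <- config$inputs[[field]]
  assert_that(!is.null(path), sprintf("config lacks inputs$%s", field))
  assert_that(file.exists(path), sprintf("missing input file: %s", path))
  path
}

#' Run one stage (or all stages) of the discovery pipeline
#'
#' Stages mirror the discovery workflow and write their artifacts under
#' `config$out_dir`:
#' \describe{
#'   \item{`simulate`}{generate a synthetic cohort + reactivity and write
#'     every input format (then usable as `inputs`).}
#'   \item{`call-reactivity`}{binarize ELISpot wells, write
#'     `groupings.tsv` and `patterns.tsv`.}
#'   \item{`segregate`}{score all clone x site pairs, write
#'     `segregation.tsv`.}
#'   \item{`annotate`}{classify sites on the transcript model, write
#'     `annotations.tsv` and an annotated `annotated.vcf`.}
#'   \item{`design-peptides`}{variant-centered 15-mer sets plus the k-mer
#'     ladder of the top candidate per clone, write `peptides.tsv/.fasta`.}
#'   \item{`motif-filter`}{anchor-motif filter over `peptides.tsv`, write
#'     `motif_filtered.tsv`.}
#'   \item{`frequency`}{per-alt + pooled carrier report, write
#'     `frequency.tsv`.}
#'   \item{`run-all`}{chain everything in memory and write all artifacts
#'     plus `candidates.tsv` and a run `manifest.json`.}
#' }
#'
#' Every filter logs record counts in/out (to stderr), and a manifest
#' records the configuration, seed and package version, so re-runs with an
#' identical configuration reproduce identical primary outputs.
#'
#' @param config A configuration list ([read_config()]) or a YAML path.
#' @param stage One of the stage names above.
#' @return Stage-dependent, invisibly: the `run-all` stage returns a list
#'   with the screen object, groupings, peptides and frequency report.
#' @export
run_pipeline <- function(config = default_config(),
                         stage = c("run-all", "simulate", "call-reactivity",
                                   "segregate", "annotate", "design-peptides",
                                   "motif-filter", "frequency")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    "simulate" = stage_simulate(config),
    "call-reactivity" = stage_reactivity(config),
    "segregate" = stage_segregate(config),
    "annotate" = stage_annotate(config),
    "design-peptides" = stage_peptides(config),
    "motif-filter" = stage_motif(config),
    "frequency" = stage_frequency(config),
    "run-all" = stage_run_all(config)
  )
}

stage_simulate <- function(config) {
  params <- do.call(simulation_params,
                    merge_config(list(seed = config$seed), config$simulate))
  bundle <- simulate_reactivity(generate_cohort(params))
  paths <- write_cohort(bundle, config$out_dir)
  log_info("simulate: wrote %d animals x %d sites, %d clones -> %s",
           params$n_animals, params$n_sites, params$n_clones, config$out_dir)
  invisible(bundle)
}

stage_reactivity <- function(config) {
  react <- read_reactivity(require_input(config, "reactivity"))
  groupings <- derive_groupings(react, params = config_positivity(config))
  log_info("call-reactivity: %d clones in, %d mappable",
           nrow(groupings), sum(groupings$mappable))
  write_groupings(groupings, file.path(config$out_dir, "groupings.tsv"))
  patterns <- pattern_report(groupings)
  readr::write_tsv(
    dplyr::select(patterns, "clone_id", "pattern_id", "pattern",
                  "n_clones_with_pattern"),
    file.path(config$out_dir, "patterns.tsv"), progress = FALSE
  )
  invisible(groupings)
}

stage_segregate <- function(config) {
  genotypes <- read_vcf(require_input(config, "vcf"))
  groupings <- read_groupings(require_input(config, "groupings"))
  results <- segregate(genotypes, groupings)
  log_info("segregate: %d clone x site pairs scored", nrow(results))
  readr::write_tsv(results, file.path(config$out_dir, "segregation.tsv"),
                   progress = FALSE)
  invisible(results)
}

stage_annotate <- function(config) {
  genotypes <- read_vcf(require_input(config, "vcf"))
  proteome <- read_proteome(require_input(config, "proteome_fasta"),
                            require_input(config, "transcript_table"))
  ann <- annotate_variants(proteome, site_table(genotypes))
  log_info("annotate: %d sites -> %d records (%d non-synonymous)",
           dplyr::n_distinct(genotypes$site_id), nrow(ann),
           sum(ann$effect == "NONSYNONYMOUS"))
  readr::write_tsv(ann, file.path(config$out_dir, "annotations.tsv"),
                   progress = FALSE)
  write_vcf(join_annotations(genotypes, ann),
            file.path(config$out_dir, "annotated.vcf"))
  invisible(ann)
}

design_candidate_peptides <- function(candidates, proteome, config) {
  top <- candidates |>
    dplyr::filter(.data$rank == 1)
  sets <- purrr::map(seq_len(nrow(top)), function(i) {
    rec <- top[i, c("site_id", "transcript_id", "protein_pos",
                    "ref_aa", "alt_aa")]
    rec$effect <- "NONSYNONYMOUS"
    prot <- protein_with_variant(proteome, rec)
    pep <- config$peptides
    tiles <- tile_variant_15mers(prot, rec$protein_pos, flank = pep$flank,
                                 length = pep$length, overlap = pep$overlap)
    tiles$role <- "tile"
    spanning <- dplyr::filter(tiles, !is.na(.data$variant_offset))
    extra <- list()
    if (nrow(spanning) >= 2) {
      # the fine-mapping window is the intersection of two adjacent
      # stimulatory peptides (an 11-mer under the default tiling)
      shared <- intersect_stimulatory(spanning[1, ], spanning[2, ])
      kmers <- enumerate_kmers(shared, k_min = pep$k_min, k_max = pep$k_max)
      kmers$role <- "kmer"
      shared$role <- "shared_window"
      wt <- wildtype_control(shared, rec$ref_aa)
      wt$role <- "wildtype_control"
      extra <- list(shared, kmers, wt)
    }
    dplyr::bind_rows(c(list(tiles), extra)) |>
      dplyr::mutate(clone_id = top$clone_id[i], site_id = rec$site_id,
                    gene = top$gene[i])
  })
  dplyr::bind_rows(sets)
}

stage_peptides <- function(config) {
  candidates <- readr::read_tsv(
    file.path(config$out_dir, "candidates.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  proteome <- read_proteome(require_input(config, "proteome_fasta"),
                            require_input(config, "transcript_table"))
  peptides <- design_candidate_peptides(candidates, proteome, config)
  log_info("design-peptides: %d peptides for %d clone(s)",
           nrow(peptides), dplyr::n_distinct(peptides$clone_id))
  write_peptides(peptides,
                 fasta_path = file.path(config$out_dir, "peptides.fasta"),
                 tsv_path = file.path(config$out_dir, "peptides.tsv"))
  invisible(peptides)
}

lookup_motif <- function(config) {
  if (!is.null(config$motif$config)) {
    motifs <- read_motifs(config$motif$config)
    spec <- motifs[[config$motif$allele]]
    assert_that(!is.null(spec),
                sprintf("allele %s not in motif config", config$motif$allele))
    return(spec)
  }
  assert_that(identical(config$motif$allele, "Mafa-A1*063"),
              sprintf("no motif config given and allele %s is not built in",
                      config$motif$allele))
  mafa_a1_063_motif()
}

stage_motif <- function(config) {
  peptides <- readr::read_tsv(file.path(config$out_dir, "peptides.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  hits <- motif_match(peptides, lookup_motif(config))
  log_info("motif-filter: %d peptides in, %d match", nrow(hits),
           sum(hits$motif_match))
  readr::write_tsv(hits, file.path(config$out_dir, "motif_filtered.tsv"),
                   progress = FALSE)
  invisible(hits)
}

stage_frequency <- function(config) {
  genotypes <- read_vcf(require_input(config, "vcf"))
  report <- write_frequency_report(genotypes,
                                   file.path(config$out_dir, "frequency.tsv"))
  log_info("frequency: %d site rows reported", nrow(report))
  invisible(report)
}

stage_run_all <- function(config) {
  genotypes <- read_vcf(require_input(config, "vcf"))
  proteome <- read_proteome(require_input(config, "proteome_fasta"),
                            require_input(config, "transcript_table"))
  react <- read_reactivity(require_input(config, "reactivity"))

  groupings <- derive_groupings(react, params = config_positivity(config))
  log_info("run-all: %d clones, %d mappable", nrow(groupings),
           sum(groupings$mappable))
  write_groupings(groupings, file.path(config$out_dir, "groupings.tsv"))

  ann <- annotate_variants(proteome, site_table(genotypes))
  readr::write_tsv(ann, file.path(config$out_dir, "annotations.tsv"),
                   progress = FALSE)

  screen <- screen_candidates(
    genotypes, dplyr::filter(groupings, .data$mappable), ann,
    mode = config$segregation$mode,
    max_missing_frac = config$segregation$max_missing_frac
  )
  log_info("run-all: %d scored pairs -> %d ns-candidates",
           nrow(screen$results), nrow(screen$candidates))
  readr::write_tsv(screen$results, file.path(config$out_dir, "segregation.tsv"),
                   progress = FALSE)
  write_candidates(screen, file.path(config$out_dir, "candidates.tsv"))

  peptides <- design_candidate_peptides(screen$candidates, proteome, config)
  write_peptides(peptides,
                 fasta_path = file.path(config$out_dir, "peptides.fasta"),
                 tsv_path = file.path(config$out_dir, "peptides.tsv"))
  hits <- motif_match(peptides, lookup_motif(config))
  readr::write_tsv(hits, file.path(config$out_dir, "motif_filtered.tsv"),
                   progress = FALSE)
  log_info("run-all: %d peptides designed, %d motif matches",
           nrow(peptides), sum(hits$motif_match))

  freq <- write_frequency_report(genotypes,
                                 file.path(config$out_dir, "frequency.tsv"))
  write_manifest(config, file.path(config$out_dir, "manifest.json"))
  invisible(list(screen = screen, groupings = groupings, peptides = peptides,
                 motif = hits, frequency = freq))
}

write_manifest <- function(config, path) {
  manifest <- list(
    package = "mhagmap",
    version = as.character(utils::packageVersion("mhagmap")),
    seed = config$seed,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
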