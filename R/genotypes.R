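#' Read a VCF into a long genotype-calls tibble
#'
#' Parses a VCF 4.x file with per-sample `GT` fields into the package's tidy
#' genotype representation: one row per animal x variant site, with the
#' diploid call collapsed to one of four classes (`HOM_REF`, `HET`,
#' `HOM_ALT`, `MISSING`). Multiallelic records are decomposed into one
#' biallelic column per alternate allele: an animal carrying alt *j* is
#' `HET`/`HOM_ALT` in column *j* and `HOM_REF` in the sibling columns, so
#' each alternate allele can be scored as its own candidate antigen.
#'
#' Phased separators (`|`) are treated as unphased; half-calls (e.g. `0/.`)
#' and `./.` map to `MISSING`. Only single-base SNV alleles are retained;
#' records whose REF or a given ALT is not a single base are dropped with a
#' warning. Annotation INFO keys from this package's dialect (`GENE`, `TRID`,
#' `CDSPOS`) are carried into columns when present.
#'
#' Site identifiers are `"chrom:pos"` where that pair is unique in the file
#' and `"chrom:pos:ALT"` where several alternate alleles share a position,
#' keeping `site_id` unique within the table.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A tibble with columns `animal_id`, `site_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `gt`, and any recognised annotation columns.
#' @seealso [write_vcf()] for the inverse operation.
#' @export
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' write_vcf(apobec3c_frequency_panel(), vcf)
#' geno <- read_vcf(vcf)
#' dplyr::count(geno, site_id, gt)
read_vcf <- function(path) {
  assert_that(file.exists(path), sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)

  samples <- colnames(v@gt)[-1]
  if (is.null(samples) || length(samples) == 0) {
    rlang::abort("VCF has no sample columns")
  }
  if (anyDuplicated(samples)) {
    rlang::abort(sprintf(
      "duplicate sample names in VCF: %s",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")
    ))
  }

  if (nrow(fix) == 0) {
    return(empty_genotypes(samples))
  }

  fmt_has_gt <- vapply(
    strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE),
    function(x) "GT" %in% x, logical(1)
  )
  if (!all(fmt_has_gt)) {
    bad <- which(!fmt_has_gt)[1]
    rlang::abort(sprintf(
      "record %s:%s has no GT field", fix$CHROM[bad], fix$POS[bad]
    ))
  }

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = nrow(fix))
  info <- parse_info(fix$INFO)

  # decompose each record into one column per single-base alt
  recs <- purrr::map(seq_len(nrow(fix)), function(i) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    keep <- nchar(alts) == 1 & alts %in% DNA_BASES
    if (!(nchar(ref) == 1 && ref %in% DNA_BASES) || !any(keep)) {
      warning(sprintf(
        "skipping non-SNV record %s:%s", fix$CHROM[i], fix$POS[i]
      ), call. = FALSE)
      return(NULL)
    }
    alleles <- gt_to_allele_counts(gt_raw[i, ], n_alt = length(alts))
    purrr::map(which(keep), function(j) {
      tibble::tibble(
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = ref,
        alt = alts[j],
        animal_id = samples,
        gt = counts_to_class(alleles[, j]),
        gene = info$gene[i],
        transcript_id = info$transcript_id[i],
        cds_pos = info$cds_pos[i]
      )
    })
  })
  calls <- dplyr::bind_rows(purrr::flatten(purrr::compact(recs)))
  if (nrow(calls) == 0) return(empty_genotypes(samples))

  calls <- calls |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::mutate(
      site_id = if (dplyr::n_distinct(.data$alt) > 1) {
        paste0(.data$chrom, ":", .data$pos, ":", .data$alt)
      } else {
        paste0(.data$chrom, ":", .data$pos)
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "animal_id", "site_id", "chrom", "pos", "ref", "alt", "gt",
      "gene", "transcript_id", "cds_pos"
    )
  if (all(is.na(calls$gene)) && all(is.na(calls$transcript_id))) {
    calls$gene <- NULL
    calls$transcript_id <- NULL
    calls$cds_pos <- NULL
  }
  validate_genotypes(calls)
}

empty_genotypes <- function(samples) {
  tibble::tibble(
    animal_id = character(), site_id = character(),
    chrom = character(), pos = integer(),
    ref = character(), alt = character(), gt = character()
  )
}

parse_info <- function(info) {
  get_key <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  list(
    gene = get_key("GENE"),
    transcript_id = get_key("TRID"),
    cds_pos = suppressWarnings(as.integer(get_key("CDSPOS")))
  )
}

# per-sample allele-j copy counts from GT strings; NA row when any field is "."
gt_to_allele_counts <- function(gt, n_alt) {
  out <- matrix(NA_integer_, nrow = length(gt), ncol = n_alt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  for (s in seq_along(parts)) {
    p <- parts[[s]]
    if (length(p) == 0 || anyNA(p) || any(p == ".") || is.na(gt[s])) next
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) next
    for (j in seq_len(n_alt)) out[s, j] <- sum(a == j)
  }
  out
}

counts_to_class <- function(copies) {
  dplyr::case_when(
    is.na(copies) ~ "MISSING",
    copies == 0L ~ "HOM_REF",
    copies == 1L ~ "HET",
    TRUE ~ "HOM_ALT"
  )
}

#' Write a genotype-calls tibble as a VCF
#'
#' Emits one biallelic record per site, so `read_vcf(write_vcf(g))`
#' reproduces `g` exactly (decomposed multiallelic sites become sibling
#' biallelic records at the same position and regain their `:ALT`-suffixed
#' identifiers on re-read). `MISSING` calls are written as `./.`.
#'
#' @param genotypes A genotype-calls tibble as returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  validate_genotypes(genotypes)
  con <- tryCatch(file(path, "w"), error = function(e) {
    rlang::abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  animals <- unique(genotypes$animal_id)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TRID,Number=1,Type=String,Description=\"Transcript id\">",
    "##INFO=<ID=CDSPOS,Number=1,Type=Integer,Description=\"1-based CDS position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", animals), collapse = "\t")
  ), con)
  if (nrow(genotypes) == 0) return(invisible(path))

  sites <- site_table(genotypes)
  gt_str <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")
  wide <- genotypes |>
    dplyr::select("animal_id", "site_id", "gt") |>
    tidyr::pivot_wider(names_from = "animal_id", values_from = "gt")
  wide <- wide[match(sites$site_id, wide$site_id), , drop = FALSE]

  info <- rep(".", nrow(sites))
  if ("gene" %in% names(sites)) {
    info <- purrr::pmap_chr(
      list(sites$gene, sites$transcript_id, sites$cds_pos),
      function(g, tr, cp) {
        kv <- c(
          if (!is.na(g)) paste0("GENE=", g),
          if (!is.na(tr)) paste0("TRID=", tr),
          if (!is.na(cp)) paste0("CDSPOS=", cp)
        )
        if (length(kv)) paste(kv, collapse = ";") else "."
      }
    )
  }
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], sites$site_id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", info[i], "GT",
            gt_str[unlist(wide[i, animals])]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' One row per variant site of a genotype-calls tibble
#'
#' @param genotypes A genotype-calls tibble.
#' @return A tibble of distinct sites ordered by chromosome and position.
#' @export
site_table <- function(genotypes) {
  keep <- intersect(
    c("site_id", "chrom", "pos", "ref", "alt", "gene", "transcript_id", "cds_pos"),
    names(genotypes)
  )
  genotypes |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keep))) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
}

#' Validate a genotype-calls tibble
#'
#' Checks the structural invariants of the tidy genotype representation:
#' required columns, calls restricted to the four genotype classes,
#' single-base distinct ref/alt alleles, positive 1-based positions,
#' consistent site metadata per `site_id`, and a complete animal x site grid.
#'
#' @param genotypes A candidate genotype-calls tibble.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_genotypes <- function(genotypes) {
  need <- c("animal_id", "site_id", "chrom", "pos", "ref", "alt", "gt")
  missing_cols <- setdiff(need, names(genotypes))
  assert_that(length(missing_cols) == 0,
              sprintf("genotype table lacks columns: %s",
                      paste(missing_cols, collapse = ", ")))
  assert_that(all(genotypes$gt %in% GT_CLASSES),
              "genotype calls must be HOM_REF/HET/HOM_ALT/MISSING")
  if (nrow(genotypes) == 0) return(invisible(genotypes))
  assert_that(all(genotypes$pos >= 1), "positions must be 1-based (>= 1)")
  sites <- dplyr::distinct(genotypes, .data$site_id, .data$chrom, .data$pos,
                           .data$ref, .data$alt)
  assert_that(!anyDuplicated(sites$site_id),
              "site metadata inconsistent within a site_id")
  assert_that(all(sites$ref %in% DNA_BASES) && all(sites$alt %in% DNA_BASES),
              "ref/alt alleles must be single bases in {A,C,G,T}")
  assert_that(all(sites$ref != sites$alt), "ref and alt alleles must differ")
  counts <- dplyr::count(genotypes, .data$site_id, .data$animal_id)
  assert_that(all(counts$n == 1) &&
                nrow(counts) == nrow(sites) * dplyr::n_distinct(genotypes$animal_id),
              "genotype table must hold exactly one call per animal x site")
  invisible(genotypes)
}
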