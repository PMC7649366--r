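Package: mhagmap
Title: Minor Histocompatibility Antigen Discovery by Genotype Segregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidy pipeline for mapping minor histocompatibility antigens
    (mHAgs) in MHC-identical cohorts: binary alloreactivity typing of T cell
    clones from IFN-gamma ELISpot count tables, exome-wide genotype
    segregation scoring between mHAg-positive and mHAg-negative animals,
    synonymous/non-synonymous annotation on a transcript model,
    variant-centered overlapping-peptide design with minimal-epitope
    enumeration, MHC class I anchor-motif filtering, and cohort carrier and
    allele frequency summaries. Includes a fully ground-truthed synthetic
    cohort generator (genotypes with configurable error and missingness,
    proteome and transcript models with planted causal non-synonymous SNPs,
    and ELISpot-like count tables) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
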