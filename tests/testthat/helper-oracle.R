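# Independent brute-force oracles, written as plain per-animal loops so they
# share no code path with the vectorised implementations they check.

oracle_site_score <- function(calls_pos, calls_neg) {
  pts <- function(g) {
    if (g == "HOM_ALT") return(5)
    if (g == "HET") return(3)
    0
  }
  carries <- function(g) g == "HET" || g == "HOM_ALT"
  pp <- 0; np <- 0; pc <- 0; nc <- 0; miss <- 0
  for (g in calls_pos) {
    pp <- pp + pts(g)
    pc <- pc + carries(g)
    if (g == "MISSING") miss <- miss + 1
  }
  for (g in calls_neg) {
    np <- np + pts(g)
    nc <- nc + carries(g)
    if (g == "MISSING") miss <- miss + 1
  }
  excl <- if (nc == 0 && pc == length(calls_pos)) {
    "PERFECT"
  } else if (nc == 0 && pc >= 1) {
    "EXCLUSIVE"
  } else {
    "NON_EXCLUSIVE"
  }
  list(pos_points = pp, neg_points = np, score = pp - np,
       exclusivity = excl, n_missing = miss)
}

oracle_carrier_counts <- function(gt_calls) {
  n_carrier <- 0; n_missing <- 0; n_het <- 0; n_hom_alt <- 0; n_hom_ref <- 0
  for (g in gt_calls) {
    if (g == "MISSING") n_missing <- n_missing + 1
    if (g == "HET") { n_het <- n_het + 1; n_carrier <- n_carrier + 1 }
    if (g == "HOM_ALT") { n_hom_alt <- n_hom_alt + 1; n_carrier <- n_carrier + 1 }
    if (g == "HOM_REF") n_hom_ref <- n_hom_ref + 1
  }
  typed <- length(gt_calls) - n_missing
  list(
    n_hom_ref = n_hom_ref, n_het = n_het, n_hom_alt = n_hom_alt,
    n_missing = n_missing, n_carriers = n_carrier,
    carrier_frac = if (typed > 0) n_carrier / typed else NA_real_,
    alt_allele_freq = if (typed > 0) (n_het + 2 * n_hom_alt) / (2 * typed)
                      else NA_real_
  )
}

# exhaustive substring enumeration, independent of enumerate_kmers
oracle_all_kmers <- function(window, k_min, k_max) {
  out <- character(0)
  for (k in k_min:k_max) {
    if (k > nchar(window)) next
    for (s in 1:(nchar(window) - k + 1)) {
      out <- c(out, substr(window, s, s + k - 1))
    }
  }
  out
}
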