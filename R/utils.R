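# Genotype classes used throughout; order matters for factor-free sorting.
GT_CLASSES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

EXCLUSIVITY_LEVELS <- c("PERFECT", "EXCLUSIVE", "NON_EXCLUSIVE")

EFFECT_LEVELS <- c("SYNONYMOUS", "NONSYNONYMOUS", "NONSENSE", "NON_CODING")

DNA_BASES <- c("A", "C", "G", "T")

# round-half-up (not banker's rounding); percent reports use 2 decimals
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

# stage logging goes to stderr so piped stdout artifacts stay clean
log_info <- function(...) {
  message(sprintf(...))
}
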