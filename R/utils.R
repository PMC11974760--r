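# Internal helpers shared across modules.

# The 20 proteinogenic amino acids, in the conventional single-letter order
# used for logo matrices.
AA_ALPHABET20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

ISOTYPES <- c("IgM", "IgG", "IgA", "IgE", "IgD", "unknown")

.repdrift_env <- new.env(parent = emptyenv())

# codon lists per amino acid, derived once from the standard genetic code
codons_by_aa <- function() {
  if (is.null(.repdrift_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    tab <- split(names(gc), unname(gc))
    .repdrift_env$codons <- tab[AA_ALPHABET20]
  }
  .repdrift_env$codons
}

# Sample one codon per amino-acid character; vectorized over `aa_chars`.
sample_codons <- function(aa_chars) {
  cod <- codons_by_aa()
  out <- character(length(aa_chars))
  for (aa in unique(aa_chars)) {
    idx <- which(aa_chars == aa)
    choices <- cod[[aa]]
    if (is.null(choices)) {
      stop("no codon for amino acid '", aa, "'", call. = FALSE)
    }
    out[idx] <- choices[sample.int(length(choices), length(idx), replace = TRUE)]
  }
  out
}

# Translate nucleotide strings; returns NA for strings that cannot be
# translated (wrong length, non-ACGT characters).
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) > 0 & nchar(nt) %% 3 == 0 &
    grepl("^[ACGT]+$", nt)
  if (any(ok)) {
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]),
      no.init.codon = TRUE
    )
    out[ok] <- as.character(aa)
  }
  out
}

# Strip the allele suffix from a V/J call: "IGHV1-69*02" -> "IGHV1-69".
gene_level <- function(call) {
  toupper(sub("\\*.*$", "", call))
}

is_prob_vector <- function(x, tol = 1e-9) {
  is.numeric(x) && length(x) > 0 && all(is.finite(x)) && all(x >= 0) &&
    abs(sum(x) - 1) <= tol
}

check_prob <- function(x, field, tol = 1e-9) {
  if (!is_prob_vector(x, tol)) {
    stop("configuration error: '", field,
         "' must be a nonnegative numeric vector summing to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 ||
      x != as.integer(x)) {
    stop("configuration error: '", field, "' must be a count >= 1",
         call. = FALSE)
  }
  as.integer(x)
}

check_unit_interval <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("configuration error: '", field, "' must lie in [0, 1]",
         call. = FALSE)
  }
  x
}

# derive auxiliary seeds from a base seed, staying within 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * offset) %% 2147483647L)
}
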