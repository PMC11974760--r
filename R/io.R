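# AIRR-style rearrangement table I/O and validation.

AIRR_CORE_COLUMNS <- c("sequence_id", "v_call", "j_call", "junction_aa",
                       "junction_nt", "isotype", "v_mutation_count",
                       "duplicate_count")
# provenance labels are extension columns, prefixed conventions documented
# in the vignette; we keep plain names for readability
PROVENANCE_COLUMNS <- c("subject", "timepoint", "replicate")
MINIMAL_COLUMNS <- c("sequence_id", "v_call", "j_call", "junction_aa")
OPTIONAL_COLUMNS <- c("d_call", "lineage_id")

VALID_AA_RE <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

required_columns <- function(dialect) {
  switch(dialect,
    airr = c(AIRR_CORE_COLUMNS, PROVENANCE_COLUMNS),
    minimal = MINIMAL_COLUMNS,
    stop("unknown dialect: ", dialect, call. = FALSE)
  )
}

# Add derived fields every downstream module relies on.
derive_fields <- function(records) {
  records$v_gene <- gene_level(records$v_call)
  records$j_gene <- gene_level(records$j_call)
  records$cdrh3_aa <- substr(records$junction_aa, 2L,
                             nchar(records$junction_aa) - 1L)
  records$cdrh3_length <- nchar(records$cdrh3_aa)
  records
}

#' Read an annotated rearrangement table
#'
#' Reads a tab-separated table of annotated heavy-chain rearrangements,
#' validates every row, and derives the gene-level and CDRH3 fields used by
#' all downstream analyses. Validation enforces: an IMGT-style junction
#' (first residue Cys, last residue Trp/Phe, valid amino-acid alphabet, at
#' least one CDRH3 residue between the anchors), and — when `junction_nt` is
#' present — a nucleotide junction of exactly 3x the amino-acid length that
#' translates to `junction_aa`. Rows failing validation are dropped and
#' counted (see attributes `n_dropped` and `drop_reasons`); missing required
#' columns are a hard error.
#'
#' V/J calls are normalized to gene level by stripping the allele suffix at
#' the first `*` (clonotypes are defined on genes, not alleles); isotypes are
#' normalized to `IgM`/`IgG`/`IgA`/`IgE`/`IgD`, anything else becoming
#' `"unknown"`.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect `"airr"` (full column set including provenance labels
#'   `subject`, `timepoint`, `replicate`) or `"minimal"` (`sequence_id`,
#'   `v_call`, `j_call`, `junction_aa`; remaining fields defaulted).
#' @return A tibble of validated records with derived columns `v_gene`,
#'   `j_gene`, `cdrh3_aa`, `cdrh3_length`, and attributes `n_dropped` and
#'   `drop_reasons`.
#' @export
read_rearrangements <- function(path, dialect = c("airr", "minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(records) == 0 && ncol(records) == 0) {
    stop("empty file: ", path, call. = FALSE)
  }
  req <- required_columns(dialect)
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    stop("no records in file: ", path, call. = FALSE)
  }
  # default optional fields for the minimal dialect
  if (!"junction_nt" %in% names(records)) records$junction_nt <- NA_character_
  if (!"isotype" %in% names(records)) records$isotype <- "unknown"
  if (!"v_mutation_count" %in% names(records)) {
    records$v_mutation_count <- NA_character_
  }
  if (!"duplicate_count" %in% names(records)) records$duplicate_count <- "1"
  for (col in PROVENANCE_COLUMNS) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }

  records$junction_aa <- toupper(records$junction_aa)
  records$junction_nt <- toupper(records$junction_nt)
  records$v_mutation_count <- suppressWarnings(
    as.integer(records$v_mutation_count))
  records$duplicate_count <- suppressWarnings(
    as.integer(records$duplicate_count))

  iso <- records$isotype
  canon <- ISOTYPES[match(tolower(iso), tolower(ISOTYPES))]
  records$isotype <- ifelse(is.na(canon), "unknown", canon)

  reasons <- list(
    bad_call = is.na(records$v_call) | gene_level(records$v_call) == "" |
      is.na(records$j_call) | gene_level(records$j_call) == "",
    bad_junction_aa = is.na(records$junction_aa) |
      !grepl(VALID_AA_RE, records$junction_aa) |
      nchar(records$junction_aa) < 3 |
      substr(records$junction_aa, 1, 1) != "C" |
      !substr(records$junction_aa, nchar(records$junction_aa),
              nchar(records$junction_aa)) %in% c("W", "F"),
    bad_counts = (!is.na(records$v_mutation_count) &
                    records$v_mutation_count < 0) |
      is.na(records$duplicate_count) | records$duplicate_count < 1
  )
  has_nt <- !is.na(records$junction_nt)
  nt_len_ok <- has_nt & grepl("^[ACGT]+$", records$junction_nt) &
    nchar(records$junction_nt) == 3L * nchar(records$junction_aa)
  translated <- rep(NA_character_, nrow(records))
  check <- nt_len_ok & !reasons$bad_junction_aa
  translated[check] <- translate_nt(records$junction_nt[check])
  reasons$bad_junction_nt <- has_nt &
    (!nt_len_ok | (check & (is.na(translated) |
                              translated != records$junction_aa)))

  bad <- Reduce(`|`, reasons)
  bad[is.na(bad)] <- TRUE
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    counts <- vapply(reasons, function(r) sum(r & bad, na.rm = TRUE),
                     integer(1))
    message("read_rearrangements: dropped ", n_dropped, " of ", nrow(records),
            " row(s) failing validation [",
            paste(sprintf("%s=%d", names(counts)[counts > 0],
                          counts[counts > 0]), collapse = ", "), "]")
  }
  out <- derive_fields(records[!bad, , drop = FALSE])
  attr(out, "n_dropped") <- n_dropped
  attr(out, "drop_reasons") <- vapply(reasons,
                                      function(r) sum(r & bad, na.rm = TRUE),
                                      integer(1))
  out
}

#' Write an annotated rearrangement table
#'
#' Serializes records to tab-separated text using AIRR-style column names;
#' derived columns (`v_gene`, `j_gene`, `cdrh3_aa`, `cdrh3_length`) are not
#' written, as they are recomputed on load. Reading a written file recovers
#' the records field-for-field.
#'
#' @param records Tibble of rearrangement records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  cols <- c("sequence_id", PROVENANCE_COLUMNS, "v_call", "d_call", "j_call",
            "junction_aa", "junction_nt", "isotype", "v_mutation_count",
            "duplicate_count", "lineage_id")
  cols <- intersect(cols, names(records))
  readr::write_tsv(records[, cols, drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Export records to FASTA
#'
#' One entry per record; the identifier line is `sequence_id` and the
#' sequence is the junction (nucleotide by default).
#'
#' @param records Tibble of rearrangement records.
#' @param path Output file path.
#' @param sequence Which field to export: `"junction_nt"` or `"junction_aa"`.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(records, path,
                         sequence = c("junction_nt", "junction_aa")) {
  sequence <- match.arg(sequence)
  seqs <- records[[sequence]]
  if (sequence == "junction_nt") {
    x <- Biostrings::DNAStringSet(seqs)
  } else {
    x <- Biostrings::AAStringSet(seqs)
  }
  names(x) <- records$sequence_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
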