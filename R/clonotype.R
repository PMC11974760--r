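# Clonotype collapsing and set operations.
#
# A clonotype is the triple (V gene, J gene, CDRH3 amino-acid sequence):
# allele information is discarded and the CDRH3 is the IMGT junction minus
# its conserved first (Cys) and last (Trp/Phe) residues.

#' Clonotype keys for rearrangement records
#'
#' Maps each record to its clonotype identity `v_gene|j_gene|cdrh3_aa`.
#' Records differing only in allele or in the nucleotide encoding of the same
#' CDRH3 amino-acid sequence map to the same key.
#'
#' @param records Tibble of validated rearrangement records (with derived
#'   fields; see [read_rearrangements()]).
#' @param use_junction If `TRUE`, key on the full junction amino-acid
#'   sequence (anchors included) instead of the CDRH3; off by default and
#'   intended for sensitivity analysis only.
#' @return Character vector of clonotype keys, one per record.
#' @export
clonotype_key <- function(records, use_junction = FALSE) {
  if (nrow(records) == 0) stop("empty input", call. = FALSE)
  cdr <- if (use_junction) records$junction_aa else records$cdrh3_aa
  if (any(is.na(cdr) | cdr == "")) {
    stop("records with empty CDRH3 cannot be clonotyped", call. = FALSE)
  }
  paste(records$v_gene, records$j_gene, cdr, sep = "|")
}

#' Collapse records into a clonotype table
#'
#' Aggregates rearrangement records into unique clonotypes with per-clonotype
#' statistics: sequence count, number of distinct biological replicates in
#' which the clonotype was observed, isotype counts, IgG frequency, and mean
#' V-gene mutation count.
#'
#' @inheritParams clonotype_key
#' @return A tibble with one row per clonotype: `clonotype`, `v_gene`,
#'   `j_gene`, `cdrh3_aa`, `cdrh3_length`, `n_sequences` (sum of
#'   `duplicate_count`), `n_replicates_observed` (distinct
#'   subject/timepoint/replicate combinations), `n_IgM`, `n_IgG`, `n_other`,
#'   `igg_frequency`, `mean_v_mutations`.
#' @export
collapse_clonotypes <- function(records, use_junction = FALSE) {
  key <- clonotype_key(records, use_junction = use_junction)
  records <- dplyr::mutate(records, .clonotype = key)
  rep_id <- paste(records$subject, records$timepoint, records$replicate,
                  sep = ".")
  dup <- if ("duplicate_count" %in% names(records)) {
    records$duplicate_count
  } else {
    rep(1L, nrow(records))
  }
  records$.rep_id <- rep_id
  records$.dup <- dup
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$.clonotype),
    v_gene = .data$v_gene[1],
    j_gene = .data$j_gene[1],
    cdrh3_aa = .data$cdrh3_aa[1],
    cdrh3_length = nchar(.data$cdrh3_aa[1]),
    n_sequences = sum(.data$.dup),
    n_replicates_observed = dplyr::n_distinct(.data$.rep_id),
    n_IgM = sum(.data$isotype == "IgM"),
    n_IgG = sum(.data$isotype == "IgG"),
    n_other = sum(!.data$isotype %in% c("IgM", "IgG")),
    igg_frequency = mean(.data$isotype == "IgG"),
    mean_v_mutations = mean(.data$v_mutation_count),
    .groups = "drop"
  )
  dplyr::rename(out, clonotype = ".clonotype")
}

as_key_set <- function(x) {
  if (is.character(x)) return(unique(x))
  if (is.data.frame(x) && "clonotype" %in% names(x)) {
    return(unique(x$clonotype))
  }
  stop("expected a clonotype table or a character vector of keys",
       call. = FALSE)
}

#' Shared and private clonotypes between two repertoires
#'
#' Partitions the union of two clonotype sets into shared and
#' repertoire-private subsets (the Venn of two timepoints or samples).
#'
#' @param a,b Clonotype tables from [collapse_clonotypes()] or character
#'   vectors of clonotype keys.
#' @return A list with character-vector elements `shared`, `only_a`,
#'   `only_b`; the three sets are disjoint and partition the union.
#' @export
shared_clonotypes <- function(a, b) {
  ka <- as_key_set(a)
  kb <- as_key_set(b)
  list(
    shared = intersect(ka, kb),
    only_a = setdiff(ka, kb),
    only_b = setdiff(kb, ka)
  )
}

#' Public clonotypes across subjects
#'
#' Clonotypes observed in every subject's repertoire ("public" in the
#' strictest, universally shared sense).
#'
#' @param tables Named list (one element per subject, at least two) of
#'   clonotype tables or key vectors.
#' @return Character vector of clonotype keys present in all subjects.
#' @export
public_clonotypes <- function(tables) {
  if (!is.list(tables) || length(tables) < 2) {
    stop("publicness requires clonotype tables from at least 2 subjects",
         call. = FALSE)
  }
  Reduce(intersect, lapply(tables, as_key_set))
}

#' Write a clonotype table to TSV
#'
#' @param table A clonotype table from [collapse_clonotypes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}
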