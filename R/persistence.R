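# Sequence- and clonotype-level turnover/persistence between timepoints,
# sharing-vs-depth diagnostics, and characterization of persistent and
# public clonotypes.

species_at_level <- function(x, level) {
  if (is.character(x)) return(x)
  if (!is.data.frame(x) || nrow(x) == 0) stop("empty input", call. = FALSE)
  switch(level,
    clonotype = clonotype_key(x),
    sequence = {
      nt <- x$junction_nt
      if (any(is.na(nt))) {
        stop("sequence-level analysis requires junction_nt on every record",
             call. = FALSE)
      }
      nt
    },
    stop("level must be 'clonotype' or 'sequence'", call. = FALSE)
  )
}

#' Turnover and persistence between two timepoints
#'
#' Counts the species appearing (present only at timepoint 2), disappearing
#' (present only at timepoint 1) and shared between two repertoire samples,
#' and derives:
#' \deqn{\mathrm{turnover\%} = 100 \cdot
#'   \frac{\mathrm{appearing} + \mathrm{disappearing}}{\mathrm{total}}}
#' \deqn{\mathrm{persistence\%} = 100 - \mathrm{turnover\%}
#'   = 100 \cdot \mathrm{shared} / \mathrm{total}}
#' where `total` is the number of distinct species in the union of the two
#' samples. The species unit is either the clonotype (V gene, J gene, CDRH3
#' amino acids) or the exact junction nucleotide sequence.
#'
#' @param t1,t2 Record tibbles for the two timepoints, or character vectors
#'   of species labels.
#' @param level `"clonotype"` or `"sequence"`.
#' @return A one-row tibble: `level`, `n_t1`, `n_t2`, `n_shared`,
#'   `n_appearing`, `n_disappearing`, `n_total`, `turnover_pct`,
#'   `persistence_pct`.
#' @export
persistence_report <- function(t1, t2, level = c("clonotype", "sequence")) {
  level <- match.arg(level)
  s1 <- unique(species_at_level(t1, level))
  s2 <- unique(species_at_level(t2, level))
  if (length(s1) == 0 || length(s2) == 0) {
    stop("both timepoints must be nonempty", call. = FALSE)
  }
  shared <- length(intersect(s1, s2))
  appearing <- length(s2) - shared
  disappearing <- length(s1) - shared
  total <- shared + appearing + disappearing
  turnover <- 100 * (appearing + disappearing) / total
  tibble::tibble(
    level = level,
    n_t1 = length(s1), n_t2 = length(s2),
    n_shared = shared, n_appearing = appearing,
    n_disappearing = disappearing, n_total = total,
    turnover_pct = turnover,
    persistence_pct = 100 - turnover
  )
}

#' Shared fraction versus sampling depth
#'
#' Bootstrap diagnostic of how observed between-timepoint sharing grows with
#' sampling depth: at each depth, both timepoints are subsampled with
#' replacement and the fraction of distinct timepoint-1 species also present
#' in the timepoint-2 subsample is recorded. Observed sharing rises with
#' depth, which is why raw shared fractions underestimate true repertoire
#' persistence at any finite depth.
#'
#' @inheritParams persistence_report
#' @param depths Integer vector of sampling depths (each >= 10).
#' @param n_boot Bootstrap resamples per depth (default 20).
#' @param seed Optional seed.
#' @return A tibble per depth: `depth`, `mean_shared_fraction`, `ci_lower`,
#'   `ci_upper`, `n_boot`.
#' @export
sharing_vs_depth <- function(t1, t2, depths, n_boot = 20, seed = NULL,
                             level = c("clonotype", "sequence")) {
  level <- match.arg(level)
  if (length(depths) == 0) stop("depth grid is empty", call. = FALSE)
  if (any(depths < 10)) stop("depths must be >= 10", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  k1 <- species_at_level(t1, level)
  k2 <- species_at_level(t2, level)
  run <- function() {
    rows <- lapply(sort(depths), function(d) {
      fr <- vapply(seq_len(n_boot), function(b) {
        s1 <- unique(k1[sample.int(length(k1), d, replace = TRUE)])
        s2 <- unique(k2[sample.int(length(k2), d, replace = TRUE)])
        mean(s1 %in% s2)
      }, numeric(1))
      ci <- stats::quantile(fr, c(0.025, 0.975), names = FALSE)
      tibble::tibble(depth = d, mean_shared_fraction = mean(fr),
                     ci_lower = min(ci[1], mean(fr)),
                     ci_upper = max(ci[2], mean(fr)), n_boot = n_boot)
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Position-by-amino-acid logo matrix
#'
#' Per-position amino-acid frequencies of CDRH3 sequences of a fixed length,
#' the numeric backbone of a sequence logo.
#'
#' @param cdrh3_aa Character vector of CDRH3 amino-acid sequences.
#' @param cdrh3_length The length to select; sequences of other lengths are
#'   ignored.
#' @return A 20 x `cdrh3_length` matrix (rows: amino acids, columns:
#'   positions); every column sums to 1.
#' @export
logo_matrix <- function(cdrh3_aa, cdrh3_length) {
  sel <- cdrh3_aa[!is.na(cdrh3_aa) & nchar(cdrh3_aa) == cdrh3_length]
  if (length(sel) == 0) {
    stop("no CDRH3 sequences of length ", cdrh3_length, call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(sel, "")), nrow = length(sel),
                  byrow = TRUE)
  m <- vapply(seq_len(cdrh3_length), function(p) {
    tab <- table(factor(chars[, p], levels = AA_ALPHABET20))
    as.numeric(tab) / length(sel)
  }, numeric(20))
  dimnames(m) <- list(AA_ALPHABET20, paste0("pos", seq_len(cdrh3_length)))
  m
}

# per-clonotype aggregates used by the group characterizations
.clonotype_profile <- function(records) {
  records$.clonotype <- clonotype_key(records)
  records$.rep_id <- paste(records$timepoint, records$replicate, sep = ".")
  dplyr::summarise(
    dplyr::group_by(records, .data$.clonotype),
    cdrh3_aa = .data$cdrh3_aa[1],
    cdrh3_length = nchar(.data$cdrh3_aa[1]),
    igg_frequency = mean(.data$isotype == "IgG"),
    mean_v_mutations = mean(.data$v_mutation_count),
    multi_replicate = max(tapply(.data$.rep_id, .data$timepoint,
                                 dplyr::n_distinct)) > 1,
    .groups = "drop"
  )
}

.rank_tests <- function(profile, group_col = "group",
                        positive = "shared", negative = "unshared") {
  metrics <- c("cdrh3_length", "igg_frequency", "mean_v_mutations",
               "multi_replicate")
  g <- profile[[group_col]]
  rows <- lapply(metrics, function(mname) {
    xs <- as.numeric(profile[[mname]][g == positive])
    xu <- as.numeric(profile[[mname]][g == negative])
    if (length(xs) == 0 || length(xu) == 0) {
      return(tibble::tibble(metric = mname, median_shared = NA_real_,
                            median_unshared = NA_real_,
                            mean_shared = NA_real_, mean_unshared = NA_real_,
                            p_value = NA_real_))
    }
    wt <- suppressWarnings(stats::wilcox.test(xs, xu, exact = FALSE))
    tibble::tibble(
      metric = mname,
      median_shared = stats::median(xs), median_unshared = stats::median(xu),
      mean_shared = mean(xs), mean_unshared = mean(xu),
      p_value = wt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Characterize persistent (shared) versus transient clonotypes
#'
#' Splits the clonotypes observed across two timepoints into those shared
#' between timepoints and those seen at only one, then compares the groups
#' on CDRH3 length, per-clonotype IgG frequency, mean V-gene mutation count,
#' and multi-replicate occurrence (observed in more than one biological
#' replicate at a single timepoint, which implies clonal expansion since
#' biological replicates derive from distinct cells). Group comparisons use
#' two-sided Mann-Whitney rank tests with Benjamini-Hochberg correction
#' across the four metrics. CDRH3 sequence-logo matrices are computed per
#' group at a fixed length.
#'
#' @param t1,t2 Record tibbles for the two timepoints.
#' @param logo_length CDRH3 length for the logo matrices (default 13).
#' @return A list: `clonotypes` (per-clonotype profile with a `group`
#'   column), `tests` (rank-test table), `logos` (list with `shared` and
#'   `unshared` matrices, `NULL` where a group has no CDRH3 of
#'   `logo_length`), `logo_length`.
#' @export
characterize_persistent <- function(t1, t2, logo_length = 13) {
  if (nrow(t1) == 0 || nrow(t2) == 0) {
    stop("both timepoints must be nonempty", call. = FALSE)
  }
  shared <- intersect(unique(clonotype_key(t1)), unique(clonotype_key(t2)))
  pooled <- dplyr::bind_rows(t1, t2)
  profile <- .clonotype_profile(pooled)
  profile$group <- ifelse(profile$.clonotype %in% shared,
                          "shared", "unshared")
  profile <- dplyr::rename(profile, clonotype = ".clonotype")
  tests <- .rank_tests(profile)
  logos <- lapply(c(shared = "shared", unshared = "unshared"), function(gr) {
    aa <- profile$cdrh3_aa[profile$group == gr]
    if (!any(nchar(aa) == logo_length)) return(NULL)
    logo_matrix(aa, logo_length)
  })
  list(clonotypes = profile, tests = tests, logos = logos,
       logo_length = logo_length)
}

#' Persistent public clonotypes across subjects and timepoints
#'
#' Identifies public clonotypes (present in every subject, pooling each
#' subject's timepoints) and splits them into persistent public clonotypes —
#' those additionally observed at both timepoints — and non-persistent
#' public clonotypes. With `mode = "all_subjects"` (default) a public
#' clonotype counts as persistent only if it is present at both timepoints
#' of every subject; `"any_subject"` requires persistence in at least one
#' subject.
#'
#' @param records Tibble of records for all subjects and timepoints (needs
#'   `subject` and `timepoint` columns; at least 2 subjects).
#' @param mode Persistence universe, see above.
#' @param logo_length CDRH3 length for logo matrices (default 13).
#' @return A list: `public`, `persistent_public`, `non_persistent_public`
#'   (key vectors), `lengths` (tibble of CDRH3 lengths per group),
#'   `length_test` (Mann-Whitney comparison of the two length
#'   distributions), `logos` (per-group logo matrices or `NULL`),
#'   `logo_length`.
#' @export
persistent_public <- function(records,
                              mode = c("all_subjects", "any_subject"),
                              logo_length = 13) {
  mode <- match.arg(mode)
  subjects <- unique(records$subject)
  if (length(subjects) < 2) {
    stop("publicness requires at least 2 subjects", call. = FALSE)
  }
  records$.clonotype <- clonotype_key(records)
  by_subject <- split(records, records$subject)
  keys_all <- lapply(by_subject, function(s) unique(s$.clonotype))
  public <- Reduce(intersect, keys_all)
  persistent_sets <- lapply(by_subject, function(s) {
    tps <- unique(s$timepoint)
    if (length(tps) < 2) return(character(0))
    Reduce(intersect, lapply(split(s$.clonotype, s$timepoint), unique))
  })
  persistent_universe <- switch(mode,
    all_subjects = Reduce(intersect, persistent_sets),
    any_subject = Reduce(union, persistent_sets)
  )
  pp <- intersect(public, persistent_universe)
  npp <- setdiff(public, pp)

  key_info <- dplyr::distinct(
    records[records$.clonotype %in% public,
            c(".clonotype", "cdrh3_aa", "cdrh3_length")]
  )
  key_info <- key_info[!duplicated(key_info$.clonotype), , drop = FALSE]
  key_info$group <- ifelse(key_info$.clonotype %in% pp,
                           "persistent_public", "non_persistent_public")
  lengths <- tibble::tibble(
    clonotype = key_info$.clonotype,
    group = key_info$group,
    cdrh3_length = key_info$cdrh3_length
  )
  lp <- lengths$cdrh3_length[lengths$group == "persistent_public"]
  ln <- lengths$cdrh3_length[lengths$group == "non_persistent_public"]
  length_test <- if (length(lp) > 0 && length(ln) > 0) {
    wt <- suppressWarnings(stats::wilcox.test(lp, ln, exact = FALSE))
    tibble::tibble(metric = "cdrh3_length",
                   median_persistent_public = stats::median(lp),
                   median_non_persistent_public = stats::median(ln),
                   p_value = wt$p.value)
  } else {
    tibble::tibble(metric = "cdrh3_length",
                   median_persistent_public = NA_real_,
                   median_non_persistent_public = NA_real_,
                   p_value = NA_real_)
  }
  logos <- lapply(c(persistent_public = "persistent_public",
                    non_persistent_public = "non_persistent_public"),
                  function(gr) {
    aa <- key_info$cdrh3_aa[key_info$group == gr]
    if (!any(nchar(aa) == logo_length)) return(NULL)
    logo_matrix(aa, logo_length)
  })
  list(public = public, persistent_public = pp, non_persistent_public = npp,
       lengths = lengths, length_test = length_test, logos = logos,
       logo_length = logo_length)
}
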