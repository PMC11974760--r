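# Morisita-Horn repertoire similarity over (V gene, J gene, CDRH3 length)
# species, with bootstrap rarefaction, pairwise matrices, clustering and
# stratified comparisons.

species_key_of <- function(records) {
  paste(records$v_gene, records$j_gene, records$cdrh3_length, sep = "|")
}

#' Reduce records to a species distribution
#'
#' Collapses rearrangement records to counts over (V gene, J gene, CDRH3
#' length) "species" — the higher-order classification that plays the role of
#' species in ecological similarity analyses of repertoires.
#'
#' @param records Tibble of validated rearrangement records.
#' @param weight_by_duplicates If `TRUE`, each record contributes its
#'   `duplicate_count`; default is unweighted (each record counts once).
#' @return A tibble with columns `v_gene`, `j_gene`, `cdrh3_length`,
#'   `count`; `sum(count)` equals the number of records (or total duplicate
#'   count).
#' @export
species_reduce <- function(records, weight_by_duplicates = FALSE) {
  if (nrow(records) == 0) stop("empty input", call. = FALSE)
  records$.w <- if (weight_by_duplicates) records$duplicate_count else 1L
  dplyr::summarise(
    dplyr::group_by(records, .data$v_gene, .data$j_gene, .data$cdrh3_length),
    count = sum(.data$.w),
    .groups = "drop"
  )
}

as_species_vector <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x) && "count" %in% names(x)) {
    key <- if (all(c("v_gene", "j_gene", "cdrh3_length") %in% names(x))) {
      paste(x$v_gene, x$j_gene, x$cdrh3_length, sep = "|")
    } else if ("species" %in% names(x)) {
      x$species
    } else {
      stop("species table must have v_gene/j_gene/cdrh3_length or 'species'",
           call. = FALSE)
    }
    return(stats::setNames(x$count, key))
  }
  stop("expected a named count vector or a species table", call. = FALSE)
}

#' Morisita-Horn similarity index
#'
#' Abundance-weighted ecological similarity between two species count
#' distributions:
#' \deqn{C_H = \frac{2 \sum_i x_i y_i}{\left(\sum_i x_i^2 / X^2 +
#'   \sum_i y_i^2 / Y^2\right) X Y}}
#' where \eqn{x_i, y_i} are the counts of species \eqn{i} in samples of total
#' size \eqn{X} and \eqn{Y}, and the sum runs over the union of species
#' observed in either sample (species absent from one side contribute
#' \eqn{x_i y_i = 0}). The index is symmetric, equals 1 for identical
#' relative distributions and 0 for disjoint species sets, and is invariant
#' to uniform scaling of one side's counts.
#'
#' @param x,y Species tables from [species_reduce()] or named count vectors.
#' @return A number in \[0, 1\].
#' @export
morisita_horn <- function(x, y) {
  xv <- as_species_vector(x)
  yv <- as_species_vector(y)
  X <- sum(xv)
  Y <- sum(yv)
  if (X <= 0 || Y <= 0) {
    stop("zero-total species distribution", call. = FALSE)
  }
  common <- intersect(names(xv), names(yv))
  cross <- sum(as.numeric(xv[common]) * as.numeric(yv[common]))
  ch <- 2 * cross / ((sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y)
  # floating-point evaluation can stray from the exact bounds by <= 1e-12;
  # identical relative distributions must report exactly 1
  ch <- min(max(ch, 0), 1)
  if (1 - ch < 1e-12) ch <- 1
  ch
}

mh_from_keys <- function(keys_a, keys_b) {
  morisita_horn(c(table(keys_a)), c(table(keys_b)))
}

#' Bootstrap Morisita-Horn similarity across sampling depths
#'
#' At each depth, both repertoires are independently subsampled with
#' replacement `n_boot` times, the Morisita-Horn index is computed over the
#' (V gene, J gene, CDRH3 length) species of each resampled pair, and the
#' bootstrap mean with a 2.5/97.5-percentile confidence band is reported.
#' Sampling with replacement permits depths exceeding the census size; such
#' depths are flagged in the output.
#'
#' @param records_a,records_b Tibbles of rearrangement records.
#' @param depths Integer vector of sampling depths (each >= 10).
#' @param n_boot Number of bootstrap resamples per depth (>= 2; default 20).
#' @param seed Optional integer seed for reproducible curves.
#' @return A tibble with one row per depth: `depth`, `mean_ch`, `ci_lower`,
#'   `ci_upper`, `n_boot`, `depth_exceeds_census`.
#' @export
subsampled_similarity <- function(records_a, records_b, depths, n_boot = 20,
                                  seed = NULL) {
  if (length(depths) == 0) stop("depth grid is empty", call. = FALSE)
  if (any(depths < 10)) stop("depths must be >= 10", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  run <- function() {
    ka <- species_key_of(records_a)
    kb <- species_key_of(records_b)
    rows <- lapply(sort(depths), function(d) {
      ch <- vapply(seq_len(n_boot), function(b) {
        mh_from_keys(ka[sample.int(length(ka), d, replace = TRUE)],
                     kb[sample.int(length(kb), d, replace = TRUE)])
      }, numeric(1))
      ci <- stats::quantile(ch, c(0.025, 0.975), names = FALSE)
      tibble::tibble(
        depth = d, mean_ch = mean(ch),
        ci_lower = min(ci[1], mean(ch)), ci_upper = max(ci[2], mean(ch)),
        n_boot = n_boot,
        depth_exceeds_census = d > length(ka) || d > length(kb)
      )
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pairwise Morisita-Horn similarity matrix
#'
#' @param samples Named list of record tibbles (e.g. one per biological
#'   replicate); see [split_replicates()].
#' @return A symmetric numeric matrix of Morisita-Horn similarities with unit
#'   diagonal, labelled by sample name.
#' @export
pairwise_similarity <- function(samples) {
  if (!is.list(samples) || length(samples) < 2 || is.null(names(samples))) {
    stop("samples must be a named list of at least 2 record collections",
         call. = FALSE)
  }
  counts <- lapply(samples, function(s) c(table(species_key_of(s))))
  k <- length(samples)
  m <- diag(1, k)
  dimnames(m) <- list(names(samples), names(samples))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- morisita_horn(counts[[i]], counts[[j]])
    }
  }
  m
}

#' Split records into per-replicate samples
#'
#' @param records Tibble with `subject`, `timepoint`, `replicate` columns.
#' @param by Provenance columns defining a sample.
#' @return Named list of record tibbles, names joining the provenance labels
#'   with `"."`.
#' @export
split_replicates <- function(records,
                             by = c("subject", "timepoint", "replicate")) {
  key <- do.call(paste, c(unname(records[by]), sep = "."))
  split(records, factor(key, levels = sort(unique(key))))
}

#' Single-linkage clustering of a similarity matrix
#'
#' Clusters the rows of a pairwise similarity matrix by single-linkage
#' hierarchical clustering. By default rows are compared with the Euclidean
#' metric on the similarity-matrix rows; alternatively `1 - similarity` can
#' be used directly as the dissimilarity. Rows are ordered lexicographically
#' by label before clustering so the result is deterministic under ties.
#'
#' @param similarity Square symmetric similarity matrix with row/column
#'   names.
#' @param metric `"euclidean"` (distance between similarity-profile rows) or
#'   `"one_minus_similarity"`.
#' @return An [stats::hclust] object.
#' @export
cluster_replicates <- function(similarity,
                               metric = c("euclidean",
                                          "one_minus_similarity")) {
  metric <- match.arg(metric)
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity)) {
    stop("similarity must be a square matrix", call. = FALSE)
  }
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  ord <- order(rownames(similarity))
  m <- similarity[ord, ord, drop = FALSE]
  d <- switch(metric,
    euclidean = stats::dist(m, method = "euclidean"),
    one_minus_similarity = stats::as.dist(1 - m)
  )
  stats::hclust(d, method = "single")
}

#' Intra- versus inter-timepoint similarity by sequence stratum
#'
#' Compares biological replicates within a subject, pairing every two
#' replicate samples and labelling the pair intra-timepoint (same timepoint)
#' or inter-timepoint. The comparison is repeated on four strata of the
#' records: all sequences, IgM sequences with fewer than two V-gene
#' nucleotide mutations (naive-enriched), IgM sequences with two or more
#' mutations, and IgG sequences.
#'
#' @param records Tibble with provenance columns.
#' @param min_records Replicate samples with fewer records than this within a
#'   stratum are excluded from that stratum.
#' @return A tibble with columns `stratum`, `comparison` (`intra`/`inter`),
#'   `n_pairs`, `median`, `q25`, `q75`; empty strata are reported with
#'   `n_pairs = 0` and `NA` summaries. The per-pair similarities are attached
#'   as attribute `"pairs"`.
#' @export
stratified_similarity <- function(records, min_records = 10) {
  strata <- list(
    all = rep(TRUE, nrow(records)),
    IgM_lt2_mutations = records$isotype == "IgM" &
      records$v_mutation_count < 2,
    IgM_ge2_mutations = records$isotype == "IgM" &
      records$v_mutation_count >= 2,
    IgG = records$isotype == "IgG"
  )
  pair_rows <- list()
  for (sname in names(strata)) {
    sub <- records[which(strata[[sname]]), , drop = FALSE]
    if (nrow(sub) == 0) next
    for (subj in unique(sub$subject)) {
      ssub <- sub[sub$subject == subj, , drop = FALSE]
      samples <- split_replicates(ssub, by = c("timepoint", "replicate"))
      samples <- samples[vapply(samples, nrow, integer(1)) >= min_records]
      if (length(samples) < 2) next
      tps <- vapply(samples, function(s) s$timepoint[1], character(1))
      keys <- lapply(samples, function(s) c(table(species_key_of(s))))
      nm <- names(samples)
      for (i in seq_len(length(samples) - 1)) {
        for (j in (i + 1):length(samples)) {
          pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
            stratum = sname, subject = subj,
            sample_a = nm[i], sample_b = nm[j],
            comparison = if (tps[i] == tps[j]) "intra" else "inter",
            ch = morisita_horn(keys[[i]], keys[[j]])
          )
        }
      }
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  grid <- tidyr::expand_grid(stratum = names(strata),
                             comparison = c("intra", "inter"))
  if (nrow(pairs) > 0) {
    summ <- dplyr::summarise(
      dplyr::group_by(pairs, .data$stratum, .data$comparison),
      n_pairs = dplyr::n(),
      median = stats::median(.data$ch),
      q25 = stats::quantile(.data$ch, 0.25, names = FALSE),
      q75 = stats::quantile(.data$ch, 0.75, names = FALSE),
      .groups = "drop"
    )
    out <- dplyr::left_join(grid, summ, by = c("stratum", "comparison"))
    out$n_pairs[is.na(out$n_pairs)] <- 0L
  } else {
    out <- dplyr::mutate(grid, n_pairs = 0L, median = NA_real_,
                         q25 = NA_real_, q75 = NA_real_)
  }
  attr(out, "pairs") <- pairs
  out
}
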