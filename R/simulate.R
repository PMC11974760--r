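#' Generate CDRH3 junctions
#'
#' Draws amino-acid junctions whose CDRH3 length (IMGT junction minus the
#' conserved anchors) follows `length_dist`, with per-position amino-acid
#' weights `aa_bias`, then backs each junction with a consistent nucleotide
#' sequence by sampling a codon for every residue. Junctions start with the
#' conserved Cys and end with the conserved Trp; codon sampling over the 20
#' amino acids guarantees no internal stop codons.
#'
#' Draws use the current RNG state; seed the session (or wrap in
#' [withr::with_seed()]) for reproducibility.
#'
#' @param n Number of junctions to draw.
#' @param length_dist Named probability vector over CDRH3 lengths (amino
#'   acids).
#' @param aa_bias Named nonnegative weights over amino acids; `NULL` for
#'   uniform.
#' @return A tibble with columns `junction_aa`, `junction_nt`,
#'   `cdrh3_length`.
#' @export
generate_junction <- function(n, length_dist, aa_bias = NULL) {
  if (length(length_dist) == 0) {
    stop("length_dist must be nonempty", call. = FALSE)
  }
  lens <- suppressWarnings(as.integer(names(length_dist)))
  if (anyNA(lens) || any(lens < 1)) {
    stop("length_dist must be named by positive integer CDRH3 lengths",
         call. = FALSE)
  }
  if (any(length_dist < 0) || sum(length_dist) <= 0) {
    stop("length_dist must be nonnegative with positive mass", call. = FALSE)
  }
  if (is.null(aa_bias)) {
    aa_bias <- stats::setNames(rep(1, 20), AA_ALPHABET20)
  }
  check_aa_bias(aa_bias, "aa_bias")
  w <- stats::setNames(rep(0, 20), AA_ALPHABET20)
  w[names(aa_bias)] <- aa_bias
  w <- w / sum(w)

  cdrh3_len <- lens[sample.int(length(lens), n, replace = TRUE,
                               prob = length_dist)]
  junction_aa <- character(n)
  junction_nt <- character(n)
  for (L in sort(unique(cdrh3_len))) {
    idx <- which(cdrh3_len == L)
    core <- matrix(sample(AA_ALPHABET20, length(idx) * L, replace = TRUE,
                          prob = w),
                   nrow = length(idx), ncol = L)
    jm <- cbind(rep("C", length(idx)), core, rep("W", length(idx)))
    junction_aa[idx] <- do.call(paste0, as.data.frame(jm))
    cm <- matrix(sample_codons(as.vector(jm)), nrow = nrow(jm))
    junction_nt[idx] <- do.call(paste0, as.data.frame(cm))
  }
  tibble::tibble(junction_aa = junction_aa, junction_nt = junction_nt,
                 cdrh3_length = as.integer(cdrh3_len))
}

# resample synonymous codons for amino-acid junctions (same translation,
# different nucleotide encoding)
synonymous_nt <- function(aa) {
  out <- character(length(aa))
  for (L in unique(nchar(aa))) {
    idx <- which(nchar(aa) == L)
    m <- matrix(unlist(strsplit(aa[idx], ""), use.names = FALSE),
                ncol = L, byrow = TRUE)
    cm <- matrix(sample_codons(as.vector(m)), nrow = nrow(m))
    out[idx] <- do.call(paste0, as.data.frame(cm))
  }
  out
}

# discrete power-law clone sizes: P(k) ~ k^-alpha, k = 1..kmax
sample_lineage_sizes <- function(n, alpha, kmax) {
  if (n == 0) return(integer(0))
  sample.int(kmax, n, replace = TRUE, prob = (seq_len(kmax))^(-alpha))
}

# resolve compartment/timepoint-specific parameters from the config
# NB: override fields are read with `[[` and exact names — `$` on a list
# partially matches (e.g. $v_gene_pool would silently pick up
# v_gene_pool_t2 when only the latter is set)
.resolve_pf <- function(config, compartment, public) {
  pf <- rep(config$persistent_fraction, length(compartment))
  mo_pf <- config$memory_overrides[["persistent_fraction"]]
  if (!is.null(mo_pf)) pf[compartment == "memory"] <- mo_pf
  po_pf <- config$public_overrides[["persistent_fraction"]]
  if (!is.null(po_pf)) pf[public] <- po_pf
  pf
}

.resolve_length_dist <- function(config, compartment) {
  mo_ld <- config$memory_overrides[["cdrh3_length_distribution"]]
  if (compartment == "memory" && !is.null(mo_ld)) {
    mo_ld
  } else {
    config$cdrh3_length_distribution
  }
}

.resolve_v_pool <- function(config, compartment, timepoint) {
  mo <- config$memory_overrides
  if (timepoint == 2L) {
    if (compartment == "memory" && !is.null(mo[["v_gene_pool_t2"]])) {
      return(mo[["v_gene_pool_t2"]])
    }
    if (!is.null(config[["v_gene_pool_t2"]])) {
      return(config[["v_gene_pool_t2"]])
    }
  }
  if (compartment == "memory" && !is.null(mo[["v_gene_pool"]])) {
    return(mo[["v_gene_pool"]])
  }
  config$v_gene_pool
}

.resolve_exponent <- function(config, compartment) {
  mo_ex <- config$memory_overrides[["lineage_size_exponent"]]
  if (compartment == "memory" && !is.null(mo_ex)) {
    mo_ex
  } else {
    config$lineage_size_exponent
  }
}

sample_named <- function(pool, n) {
  names(pool)[sample.int(length(pool), n, replace = TRUE, prob = pool)]
}

# Create `n` new lineages for one subject at one timepoint. Public lineages
# copy their clonotype (V, J, junction) from the shared pool.
.new_lineages <- function(config, n, subject, timepoint, public_pool,
                          id_start) {
  if (n == 0) {
    return(tibble::tibble(
      lineage_id = character(0), subject = character(0),
      compartment = character(0), public = logical(0),
      v_gene = character(0), d_gene = character(0), j_gene = character(0),
      junction_aa = character(0), junction_nt = character(0),
      cdrh3_length = integer(0)
    ))
  }
  compartment <- ifelse(stats::runif(n) < config$naive_fraction,
                        "naive", "memory")
  public <- stats::runif(n) < config$public_pool_weight &
    nrow(public_pool) > 0

  out <- tibble::tibble(
    lineage_id = sprintf("%s_L%06d", subject, id_start + seq_len(n) - 1L),
    subject = subject,
    compartment = compartment,
    public = public,
    v_gene = NA_character_, d_gene = NA_character_, j_gene = NA_character_,
    junction_aa = NA_character_, junction_nt = NA_character_,
    cdrh3_length = NA_integer_
  )

  # private lineages: draw genes and junctions per compartment
  for (comp in c("naive", "memory")) {
    idx <- which(!public & compartment == comp)
    if (!length(idx)) next
    vp <- .resolve_v_pool(config, comp, timepoint)
    out$v_gene[idx] <- sample_named(vp, length(idx))
    out$d_gene[idx] <- sample_named(config$d_gene_pool, length(idx))
    out$j_gene[idx] <- sample_named(config$j_gene_pool, length(idx))
    jn <- generate_junction(length(idx), .resolve_length_dist(config, comp),
                            config$junction_aa_bias)
    out$junction_aa[idx] <- jn$junction_aa
    out$junction_nt[idx] <- jn$junction_nt
    out$cdrh3_length[idx] <- jn$cdrh3_length
  }

  # public lineages: clonotype identity shared across subjects
  pidx <- which(public)
  if (length(pidx)) {
    pick <- sample.int(nrow(public_pool), length(pidx), replace = TRUE)
    out$v_gene[pidx] <- public_pool$v_gene[pick]
    out$d_gene[pidx] <- public_pool$d_gene[pick]
    out$j_gene[pidx] <- public_pool$j_gene[pick]
    out$junction_aa[pidx] <- public_pool$junction_aa[pick]
    out$junction_nt[pidx] <- public_pool$junction_nt[pick]
    out$cdrh3_length[pidx] <- public_pool$cdrh3_length[pick]
  }

  # synonymous junction encodings: memory clones carry within-clone
  # nucleotide diversity, naive clones a single encoding
  K <- config$junction_nt_variants
  vars <- matrix(out$junction_nt, nrow = nrow(out), ncol = K)
  if (K > 1) {
    mem <- which(out$compartment == "memory")
    if (length(mem)) {
      for (k in 2:K) {
        vars[mem, k] <- synonymous_nt(out$junction_aa[mem])
      }
    }
  }
  colnames(vars) <- paste0("nt_variant_", seq_len(K))
  dplyr::bind_cols(out, tibble::as_tibble(vars))
}

#' Simulate an annotated longitudinal repertoire study
#'
#' Generates heavy-chain rearrangement records for `n_subjects` subjects
#' sampled at up to two timepoints with `n_replicates` biological replicates
#' each, together with a ground-truth lineage registry. Each subject's
#' timepoint is modelled as a pool of clonal lineages; a lineage carries one
#' clonotype (V gene, J gene, CDRH3 amino-acid sequence backed by a fixed
#' junction nucleotide sequence), a compartment (naive or memory), and a
#' clone size drawn from a discrete power law. Biological replicates are
#' disjoint draws without replacement from the timepoint's cell pool, so a
#' clonotype observed in more than one replicate must come from a lineage of
#' more than one cell. A lineage present at timepoint 1 persists to timepoint
#' 2 with the configured persistent fraction; fresh lineages top the pool
#' back up. A public pool of clonotypes is shared across all subjects.
#' Memory lineages carry `junction_nt_variants` synonymous nucleotide
#' encodings of their junction (one drawn per record), so nucleotide-level
#' sequence identity strictly refines clonotype identity, as in real data.
#'
#' Naive records are IgM with zero V-gene mutations; memory records draw an
#' isotype from `memory_isotype_probs` and a Poisson V-gene mutation count
#' with mean `shm_rate`.
#'
#' All randomness flows from a single generator seeded with `config$seed`;
#' identical configurations produce identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#' \describe{
#'   \item{records}{Tibble of rearrangement records (one row per sequenced
#'     cell) with provenance labels `subject`, `timepoint`, `replicate`,
#'     AIRR-style fields (`v_call`, `j_call`, `junction_aa`, `junction_nt`,
#'     `isotype`, `v_mutation_count`, `duplicate_count`), derived gene-level
#'     fields, and the generating `lineage_id`.}
#'   \item{truth}{Ground-truth registry: one row per subject-lineage with its
#'     clonotype, compartment, public flag, timepoint membership and
#'     persistent flag, plus the public pool and the configuration.}
#' }
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(config) {
  subjects <- sprintf("S%d", seq_len(config$n_subjects))

  public_pool <- if (config$public_pool_size > 0) {
    po_ld <- config$public_overrides[["cdrh3_length_distribution"]]
    ld <- if (!is.null(po_ld)) po_ld else config$cdrh3_length_distribution
    jn <- generate_junction(config$public_pool_size, ld,
                            config$junction_aa_bias)
    tibble::tibble(
      public_id = sprintf("P%04d", seq_len(config$public_pool_size)),
      v_gene = sample_named(config$v_gene_pool, config$public_pool_size),
      d_gene = sample_named(config$d_gene_pool, config$public_pool_size),
      j_gene = sample_named(config$j_gene_pool, config$public_pool_size),
      junction_aa = jn$junction_aa, junction_nt = jn$junction_nt,
      cdrh3_length = jn$cdrh3_length
    )
  } else {
    tibble::tibble(
      public_id = character(0), v_gene = character(0), d_gene = character(0),
      j_gene = character(0), junction_aa = character(0),
      junction_nt = character(0), cdrh3_length = integer(0)
    )
  }

  all_records <- vector("list", config$n_subjects)
  all_lineages <- vector("list", config$n_subjects)

  for (si in seq_along(subjects)) {
    subj <- subjects[si]
    lin1 <- .new_lineages(config, config$n_lineages, subj, 1L, public_pool,
                          id_start = 1L)
    lin1$present_t1 <- TRUE

    if (config$n_timepoints == 2) {
      pf <- .resolve_pf(config, lin1$compartment, lin1$public)
      persists <- stats::runif(nrow(lin1)) < pf
      n_fresh <- max(0L, config$n_lineages - sum(persists))
      fresh <- .new_lineages(config, n_fresh, subj, 2L, public_pool,
                             id_start = config$n_lineages + 1L)
      fresh$present_t1 <- FALSE
      lin1$present_t2 <- persists
      fresh$present_t2 <- TRUE
      lineages <- dplyr::bind_rows(lin1, fresh)
    } else {
      lin1$present_t2 <- FALSE
      lineages <- lin1
    }
    lineages$persistent <- lineages$present_t1 & lineages$present_t2

    recs <- vector("list", config$n_timepoints)
    for (tp in seq_len(config$n_timepoints)) {
      present <- if (tp == 1L) lineages$present_t1 else lineages$present_t2
      sub <- lineages[present, , drop = FALSE]
      alpha <- ifelse(sub$compartment == "memory",
                      .resolve_exponent(config, "memory"),
                      .resolve_exponent(config, "naive"))
      # draw sizes per compartment so memory clones can be heavier-tailed
      sizes <- integer(nrow(sub))
      for (a in unique(alpha)) {
        ii <- which(alpha == a)
        sizes[ii] <- sample_lineage_sizes(length(ii), a,
                                          config$lineage_size_max)
      }
      pool <- rep.int(seq_len(nrow(sub)), sizes)
      if (config$census) {
        cells <- sample(pool)
        replicate_of <- rep(seq_len(config$n_replicates),
                            length.out = length(cells))
        replicate_of <- sample(replicate_of)
      } else {
        need <- config$n_replicates * config$n_sequences
        if (length(pool) < need) {
          stop("cell pool (", length(pool), ") smaller than requested draw (",
               need, "); increase n_lineages", call. = FALSE)
        }
        cells <- sample(pool, need, replace = FALSE)
        replicate_of <- rep(seq_len(config$n_replicates),
                            each = config$n_sequences)
      }
      n_cells <- length(cells)
      isotype <- rep("IgM", n_cells)
      v_mut <- integer(n_cells)
      mem <- sub$compartment[cells] == "memory"
      if (any(mem)) {
        isotype[mem] <- sample_named(config$memory_isotype_probs, sum(mem))
        v_mut[mem] <- stats::rpois(sum(mem), config$shm_rate)
      }
      # alleles are emitted so that loaders must normalize to gene level
      v_allele <- sample(c("*01", "*02"), n_cells, replace = TRUE)
      K <- config$junction_nt_variants
      vm <- as.matrix(sub[, paste0("nt_variant_", seq_len(K))])
      nt <- vm[cbind(cells, sample.int(K, n_cells, replace = TRUE))]
      recs[[tp]] <- tibble::tibble(
        sequence_id = sprintf("%s_T%d_%07d", subj, tp, seq_len(n_cells)),
        subject = subj,
        timepoint = sprintf("T%d", tp),
        replicate = sprintf("R%d", replicate_of),
        v_call = paste0(sub$v_gene[cells], v_allele),
        d_call = sub$d_gene[cells],
        j_call = paste0(sub$j_gene[cells], "*01"),
        junction_aa = sub$junction_aa[cells],
        junction_nt = nt,
        isotype = isotype,
        v_mutation_count = v_mut,
        duplicate_count = 1L,
        lineage_id = sub$lineage_id[cells]
      )
    }
    all_records[[si]] <- dplyr::bind_rows(recs)
    all_lineages[[si]] <- lineages
  }

  records <- dplyr::bind_rows(all_records)
  records$v_gene <- gene_level(records$v_call)
  records$j_gene <- gene_level(records$j_call)
  records$cdrh3_aa <- substr(records$junction_aa, 2L,
                             nchar(records$junction_aa) - 1L)
  records$cdrh3_length <- nchar(records$cdrh3_aa)

  list(
    records = records,
    truth = list(
      lineages = dplyr::bind_rows(all_lineages),
      public_pool = public_pool,
      config = config
    )
  )
}

#' Write the ground-truth lineage registry to TSV
#'
#' @param truth The `truth` element of a [simulate_study()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth$lineages, path)
  invisible(path)
}
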