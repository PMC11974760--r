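#' Default gene-usage pools for the repertoire simulator
#'
#' Named probability vectors over a reduced set of commonly used human
#' heavy-chain germline genes. The shapes are realistic (e.g. IGHV3-23 and
#' IGHJ4 dominant) but deliberately compact: the simulator's purpose is
#' parameter recovery, not germline completeness.
#'
#' @return A named numeric vector of usage probabilities summing to 1.
#' @name default_pools
NULL

#' @rdname default_pools
#' @export
default_v_gene_pool <- function() {
  w <- c(
    "IGHV1-2" = 3.5, "IGHV1-18" = 2.5, "IGHV1-46" = 2.5, "IGHV1-69" = 4.5,
    "IGHV2-5" = 1.5, "IGHV3-7" = 3.5, "IGHV3-9" = 3.0, "IGHV3-15" = 2.5,
    "IGHV3-21" = 4.0, "IGHV3-23" = 9.0, "IGHV3-30" = 7.0, "IGHV3-33" = 4.0,
    "IGHV3-48" = 3.5, "IGHV3-53" = 3.0, "IGHV4-31" = 3.0, "IGHV4-34" = 5.5,
    "IGHV4-39" = 5.0, "IGHV4-59" = 5.5, "IGHV5-51" = 4.5, "IGHV6-1" = 2.0
  )
  w / sum(w)
}

#' @rdname default_pools
#' @export
default_d_gene_pool <- function() {
  w <- c(
    "IGHD1-26" = 10, "IGHD2-2" = 12, "IGHD2-15" = 11, "IGHD3-3" = 12,
    "IGHD3-10" = 14, "IGHD3-22" = 11, "IGHD4-17" = 8, "IGHD5-12" = 7,
    "IGHD6-13" = 8, "IGHD6-19" = 7
  )
  w / sum(w)
}

#' @rdname default_pools
#' @export
default_j_gene_pool <- function() {
  w <- c(
    "IGHJ1" = 1.5, "IGHJ2" = 4, "IGHJ3" = 8, "IGHJ4" = 50,
    "IGHJ5" = 12, "IGHJ6" = 24.5
  )
  w / sum(w)
}

#' Default CDRH3 length distribution
#'
#' Probability mass over CDRH3 lengths 5-35 amino acids (IMGT junction minus
#' the two conserved anchors), a discretized bell shape centred near 15-16 AA
#' as observed in human peripheral repertoires.
#'
#' @param mean,sd Location and spread of the underlying normal before
#'   discretization.
#' @return Named numeric vector over lengths 5:35, summing to 1.
#' @export
default_cdrh3_length_distribution <- function(mean = 15.5, sd = 3.5) {
  lens <- 5:35
  w <- stats::dnorm(lens, mean = mean, sd = sd)
  stats::setNames(w / sum(w), lens)
}

#' Default amino-acid weights for non-templated CDRH3 positions
#'
#' Relative weights applied at every CDRH3 position between the conserved
#' anchors; glycine, tyrosine, serine, aspartate and arginine are enriched,
#' reflecting the composition bias of human CDRH3s.
#'
#' @return Named numeric vector of 20 weights (not necessarily summing to 1;
#'   they are normalized internally).
#' @export
default_junction_aa_bias <- function() {
  c(
    A = 1.0, R = 1.5, N = 0.8, D = 1.5, C = 0.3, Q = 0.6, E = 0.8, G = 2.0,
    H = 0.5, I = 0.7, L = 1.0, K = 0.7, M = 0.4, F = 0.8, P = 0.6, S = 1.5,
    T = 0.9, W = 0.6, Y = 2.0, V = 1.0
  )
}

#' Build a validated simulation configuration
#'
#' Parameterizes the synthetic longitudinal repertoire generator: the study
#' layout (subjects x timepoints x biological replicates x sequences), germline
#' gene usage, junctional diversity, the naive/memory compartment structure
#' (isotype and somatic hypermutation), clonal lineage sizes, the fraction of
#' lineages persisting between timepoints, and a public clonotype pool shared
#' across subjects.
#'
#' The defaults mirror the design the package targets: 2 subjects sampled at 2
#' timepoints with 6 biological replicates each, and a persistent fraction of
#' 0.02, i.e. the low-persistence regime of circulating human antibody
#' repertoires.
#'
#' @param n_subjects,n_timepoints,n_replicates,n_sequences Study layout.
#'   `n_timepoints` must be 1 or 2. `n_sequences` is the number of records
#'   sampled per biological replicate (ignored when `census = TRUE`).
#' @param n_lineages Number of clonal lineages in a subject's cell pool per
#'   timepoint. Default (`NULL`) is `n_replicates * n_sequences`, which makes
#'   most observed clonotypes singletons, as in deep repertoire data.
#' @param census If `TRUE`, every cell of the pool is sequenced (partitioned
#'   across replicates without replacement) so every lineage is observed;
#'   requires an explicit `n_lineages`.
#' @param v_gene_pool,d_gene_pool,j_gene_pool Named probability vectors of
#'   germline gene usage.
#' @param cdrh3_length_distribution Named probability vector over CDRH3
#'   lengths; names must lie in 5-35 (amino acids, IMGT junction minus
#'   anchors).
#' @param junction_aa_bias Named weights over the 20 amino acids used at
#'   non-anchor CDRH3 positions.
#' @param naive_fraction Probability that a lineage is naive (IgM, zero V-gene
#'   mutations).
#' @param memory_isotype_probs Named probabilities of IgM/IgG for records of
#'   memory lineages.
#' @param shm_rate Mean number of V-gene nucleotide mutations per memory
#'   record (Poisson).
#' @param junction_nt_variants Number of synonymous junction nucleotide
#'   encodings carried by a memory lineage (each record draws one),
#'   emulating within-clone nucleotide diversity from somatic hypermutation;
#'   naive lineages carry a single encoding. Makes sequence-level
#'   (nucleotide) identity a strict refinement of clonotype identity.
#' @param lineage_size_exponent,lineage_size_max Discrete power-law lineage
#'   (clone) size model: P(k) proportional to k^-exponent for k in
#'   1..lineage_size_max.
#' @param persistent_fraction Probability that a lineage present at timepoint
#'   1 is also present at timepoint 2.
#' @param public_pool_size,public_pool_weight Size of the cross-subject public
#'   clonotype pool and the probability that a newly created lineage draws its
#'   clonotype from it.
#' @param v_gene_pool_t2 Optional alternative V-gene usage for lineages newly
#'   created at timepoint 2 (models a usage shift between timepoints).
#' @param memory_overrides Optional list overriding, for memory lineages only,
#'   any of: `cdrh3_length_distribution`, `lineage_size_exponent`,
#'   `persistent_fraction`, `v_gene_pool`, `v_gene_pool_t2`.
#' @param public_overrides Optional list overriding, for public-pool
#'   clonotypes, any of: `cdrh3_length_distribution`, `persistent_fraction`.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   simulated study exactly.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_subjects = 2,
                       n_timepoints = 2,
                       n_replicates = 6,
                       n_sequences = 1000,
                       n_lineages = NULL,
                       census = FALSE,
                       v_gene_pool = default_v_gene_pool(),
                       d_gene_pool = default_d_gene_pool(),
                       j_gene_pool = default_j_gene_pool(),
                       cdrh3_length_distribution = default_cdrh3_length_distribution(),
                       junction_aa_bias = default_junction_aa_bias(),
                       naive_fraction = 0.7,
                       memory_isotype_probs = c(IgM = 0.3, IgG = 0.7),
                       shm_rate = 6,
                       junction_nt_variants = 3,
                       lineage_size_exponent = 2.5,
                       lineage_size_max = 1000,
                       persistent_fraction = 0.02,
                       public_pool_size = 100,
                       public_pool_weight = 0.01,
                       v_gene_pool_t2 = NULL,
                       memory_overrides = list(),
                       public_overrides = list(),
                       seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_timepoints <- check_count(n_timepoints, "n_timepoints")
  if (n_timepoints > 2) {
    stop("configuration error: 'n_timepoints' must be 1 or 2", call. = FALSE)
  }
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_sequences <- check_count(n_sequences, "n_sequences")
  if (isTRUE(census) && is.null(n_lineages)) {
    stop("configuration error: census sampling requires an explicit 'n_lineages'",
         call. = FALSE)
  }
  if (is.null(n_lineages)) n_lineages <- n_replicates * n_sequences
  n_lineages <- check_count(n_lineages, "n_lineages")

  check_prob(v_gene_pool, "v_gene_pool")
  check_prob(d_gene_pool, "d_gene_pool")
  check_prob(j_gene_pool, "j_gene_pool")
  check_prob(memory_isotype_probs, "memory_isotype_probs")
  check_cdrh3_dist(cdrh3_length_distribution, "cdrh3_length_distribution")
  check_aa_bias(junction_aa_bias, "junction_aa_bias")
  naive_fraction <- check_unit_interval(naive_fraction, "naive_fraction")
  persistent_fraction <- check_unit_interval(persistent_fraction,
                                             "persistent_fraction")
  public_pool_weight <- check_unit_interval(public_pool_weight,
                                            "public_pool_weight")
  public_pool_size <- check_count(public_pool_size + 1, "public_pool_size") - 1L
  if (!is.numeric(shm_rate) || shm_rate < 0) {
    stop("configuration error: 'shm_rate' must be >= 0", call. = FALSE)
  }
  junction_nt_variants <- check_count(junction_nt_variants,
                                      "junction_nt_variants")
  if (!is.numeric(lineage_size_exponent) || lineage_size_exponent <= 1) {
    stop("configuration error: 'lineage_size_exponent' must be > 1",
         call. = FALSE)
  }
  lineage_size_max <- check_count(lineage_size_max, "lineage_size_max")
  if (!is.null(v_gene_pool_t2)) check_prob(v_gene_pool_t2, "v_gene_pool_t2")
  check_overrides(memory_overrides,
                  c("cdrh3_length_distribution", "lineage_size_exponent",
                    "persistent_fraction", "v_gene_pool", "v_gene_pool_t2"),
                  "memory_overrides")
  check_overrides(public_overrides,
                  c("cdrh3_length_distribution", "persistent_fraction"),
                  "public_overrides")
  seed <- check_count(abs(seed) + 1, "seed") - 1L

  structure(
    list(
      n_subjects = n_subjects, n_timepoints = n_timepoints,
      n_replicates = n_replicates, n_sequences = n_sequences,
      n_lineages = n_lineages, census = isTRUE(census),
      v_gene_pool = v_gene_pool, d_gene_pool = d_gene_pool,
      j_gene_pool = j_gene_pool,
      cdrh3_length_distribution = cdrh3_length_distribution,
      junction_aa_bias = junction_aa_bias,
      naive_fraction = naive_fraction,
      memory_isotype_probs = memory_isotype_probs,
      shm_rate = shm_rate,
      junction_nt_variants = junction_nt_variants,
      lineage_size_exponent = lineage_size_exponent,
      lineage_size_max = lineage_size_max,
      persistent_fraction = persistent_fraction,
      public_pool_size = public_pool_size,
      public_pool_weight = public_pool_weight,
      v_gene_pool_t2 = v_gene_pool_t2,
      memory_overrides = memory_overrides,
      public_overrides = public_overrides,
      seed = seed
    ),
    class = "sim_config"
  )
}

check_cdrh3_dist <- function(x, field) {
  if (is.null(names(x))) {
    stop("configuration error: '", field, "' must be named by CDRH3 length",
         call. = FALSE)
  }
  lens <- suppressWarnings(as.integer(names(x)))
  if (anyNA(lens) || any(lens < 5) || any(lens > 35)) {
    stop("configuration error: '", field,
         "' lengths must be integers in 5..35", call. = FALSE)
  }
  check_prob(x, field)
}

check_aa_bias <- function(x, field) {
  if (!is.numeric(x) || is.null(names(x)) ||
      !all(names(x) %in% AA_ALPHABET20) || any(x < 0) || sum(x) <= 0) {
    stop("configuration error: '", field,
         "' must be nonnegative weights named by amino acids", call. = FALSE)
  }
  invisible(x)
}

check_overrides <- function(x, allowed, field) {
  if (!is.list(x)) {
    stop("configuration error: '", field, "' must be a list", call. = FALSE)
  }
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("configuration error: unknown ", field, " field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$cdrh3_length_distribution)) {
    check_cdrh3_dist(x$cdrh3_length_distribution,
                     paste0(field, "$cdrh3_length_distribution"))
  }
  for (f in intersect(names(x), c("v_gene_pool", "v_gene_pool_t2"))) {
    check_prob(x[[f]], paste0(field, "$", f))
  }
  if (!is.null(x$persistent_fraction)) {
    check_unit_interval(x$persistent_fraction,
                        paste0(field, "$persistent_fraction"))
  }
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Key-value fields map one-to-one onto [sim_config()] arguments; named
#' vectors (gene pools, length distributions) are given as YAML mappings.
#' The result is passed through the same schema validation as [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vec_fields <- c("v_gene_pool", "d_gene_pool", "j_gene_pool",
                  "cdrh3_length_distribution", "junction_aa_bias",
                  "memory_isotype_probs", "v_gene_pool_t2")
  for (f in intersect(names(raw), vec_fields)) {
    raw[[f]] <- unlist(raw[[f]])
  }
  for (f in intersect(names(raw), c("memory_overrides", "public_overrides"))) {
    raw[[f]] <- lapply(raw[[f]], unlist)
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown)) {
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  layout: %d subject(s) x %d timepoint(s) x %d replicate(s)\n",
              x$n_subjects, x$n_timepoints, x$n_replicates))
  if (x$census) {
    cat(sprintf("  sampling: census of %d lineages per timepoint\n",
                x$n_lineages))
  } else {
    cat(sprintf("  sampling: %d sequences/replicate from %d lineages\n",
                x$n_sequences, x$n_lineages))
  }
  cat(sprintf("  naive fraction %.2f | shm rate %.1f | persistent fraction %.3f\n",
              x$naive_fraction, x$shm_rate, x$persistent_fraction))
  cat(sprintf("  public pool: %d clonotypes, weight %.3f | seed %d\n",
              x$public_pool_size, x$public_pool_weight, x$seed))
  invisible(x)
}
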