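# Shared fixtures and independent oracles for the test suite.

# deterministic reverse translation: lexicographically first codon per AA
aa_to_nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  first <- tapply(names(gc), unname(gc), function(z) sort(z)[1])
  vapply(strsplit(aa, ""), function(ch) paste0(first[ch], collapse = ""), "")
}

# hand-built, fully valid rearrangement records (tibble recycles scalars)
make_records <- function(cdrh3_aa, v_gene = "IGHV3-23", j_gene = "IGHJ4",
                         subject = "S1", timepoint = "T1", replicate = "R1",
                         isotype = "IgM", v_mutation_count = 0L,
                         duplicate_count = 1L, junction_nt = NULL,
                         id_prefix = "seq") {
  junction_aa <- paste0("C", cdrh3_aa, "W")
  if (is.null(junction_nt)) junction_nt <- aa_to_nt(junction_aa)
  n <- length(junction_aa)
  tibble::tibble(
    sequence_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    subject = subject, timepoint = timepoint, replicate = replicate,
    v_call = paste0(v_gene, "*01"), j_call = paste0(j_gene, "*01"),
    junction_aa = junction_aa, junction_nt = junction_nt,
    isotype = isotype, v_mutation_count = v_mutation_count,
    duplicate_count = duplicate_count,
    v_gene = v_gene, j_gene = j_gene, cdrh3_aa = cdrh3_aa,
    cdrh3_length = nchar(cdrh3_aa)
  )
}

# exact-arithmetic Morisita-Horn oracle: with integer counts the index is a
# ratio of (small) integers, computed here on an algebraic path independent
# of the implementation
mh_exact <- function(x, y) {
  keys <- union(names(x), names(y))
  xi <- as.numeric(x[keys]); xi[is.na(xi)] <- 0
  yi <- as.numeric(y[keys]); yi[is.na(yi)] <- 0
  X <- sum(xi); Y <- sum(yi)
  (2 * sum(xi * yi) * X * Y) / (sum(xi^2) * Y^2 + sum(yi^2) * X^2)
}

random_species_counts <- function(max_species = 10, max_count = 20,
                                  shared_pool = LETTERS[1:10]) {
  k <- sample(2:max_species, 1)
  sp <- sample(shared_pool, k)
  stats::setNames(sample.int(max_count, k, replace = TRUE), sp)
}

# exhaustive-merge single-linkage oracle: returns merge heights in order
slink_oracle_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- min(d[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# small default study used by several tests
small_study <- function(seed = 11, ...) {
  simulate_study(sim_config(n_subjects = 2, n_timepoints = 2,
                            n_replicates = 3, n_sequences = 200,
                            seed = seed, ...))
}
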