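test_that("species reduction counts (V, J, CDRH3-length) combinations", {
  recs <- dplyr::bind_rows(
    make_records(c("AAAAAAAAAAAAA", "GGGGGGGGGGGGG"), v_gene = "IGHV1-2",
                 j_gene = "IGHJ4"),
    make_records("AAAAAAAAAAAAAAA", v_gene = "IGHV1-2", j_gene = "IGHJ4"),
    make_records("YYYYYYYYYYYYY", v_gene = "IGHV3-23", j_gene = "IGHJ6")
  )
  sp <- species_reduce(recs)
  expect_equal(nrow(sp), 3)
  expect_equal(sum(sp$count), 4)
  expect_setequal(sp$count, c(2, 1, 1))
  # records differing only in CDRH3 content at equal length are one species
  expect_equal(sp$count[sp$v_gene == "IGHV1-2" & sp$cdrh3_length == 13], 2)

  one <- species_reduce(make_records(rep("ARDYW", 5)))
  expect_equal(nrow(one), 1)
  expect_equal(one$count / sum(one$count), 1)
  expect_error(species_reduce(recs[0, ]), "empty")
})

test_that("Morisita-Horn matches exact arithmetic and its limit cases", {
  # worked example: x = {A:2, B:1}, y = {A:1, B:3} -> 120/170 = 12/17
  expect_equal(morisita_horn(c(A = 2, B = 1), c(A = 1, B = 3)), 12 / 17,
               tolerance = 1e-14)
  withr::with_seed(101, {
    for (i in 1:100) {
      x <- random_species_counts()
      y <- random_species_counts()
      expect_equal(morisita_horn(x, y), mh_exact(x, y), tolerance = 1e-12)
      # symmetry
      expect_equal(morisita_horn(x, y), morisita_horn(y, x),
                   tolerance = 1e-14)
      # identity and disjointness
      expect_equal(morisita_horn(x, x), 1, tolerance = 1e-12)
      names(y) <- paste0("z", seq_along(y))
      expect_identical(morisita_horn(x, y), 0)
    }
  })
  expect_error(morisita_horn(c(A = 0), c(A = 1)), "zero-total")
})

test_that("Morisita-Horn agrees with the vegan ecology oracle", {
  skip_if_not_installed("vegan")
  withr::with_seed(103, {
    for (i in 1:25) {
      x <- random_species_counts()
      y <- random_species_counts()
      keys <- union(names(x), names(y))
      m <- rbind(ifelse(is.na(x[keys]), 0, x[keys]),
                 ifelse(is.na(y[keys]), 0, y[keys]))
      ref <- 1 - as.numeric(vegan::vegdist(m, method = "horn"))
      expect_equal(morisita_horn(x, y), ref, tolerance = 1e-10)
    }
  })
})

test_that("Morisita-Horn is invariant to relabeling and count scaling", {
  withr::with_seed(107, {
    for (i in 1:20) {
      x <- random_species_counts()
      y <- random_species_counts()
      ch <- morisita_horn(x, y)
      perm <- sample(LETTERS[1:10])
      relab <- function(v) stats::setNames(v, perm[match(names(v),
                                                         LETTERS[1:10])])
      expect_equal(morisita_horn(relab(x), relab(y)), ch, tolerance = 1e-12)
      expect_equal(morisita_horn(7 * x, y), ch, tolerance = 1e-9)
    }
  })
})

test_that("bootstrap similarity curves are deterministic and consistent", {
  sim <- small_study(seed = 51)
  a <- sim$records[sim$records$subject == "S1" &
                     sim$records$timepoint == "T1", ]
  depths <- c(10, 100, 5 * nrow(a))
  curve1 <- subsampled_similarity(a, a, depths = depths, n_boot = 10,
                                  seed = 7)
  curve2 <- subsampled_similarity(a, a, depths = depths, n_boot = 10,
                                  seed = 7)
  expect_identical(curve1, curve2)
  # self-similarity rises toward 1 with depth (with-replacement resampling
  # still misses rare species at census depth, hence the deep grid point)
  expect_gt(curve1$mean_ch[3], 0.9)
  expect_true(all(diff(curve1$mean_ch) > 0))
  expect_true(all(curve1$ci_lower <= curve1$mean_ch &
                    curve1$mean_ch <= curve1$ci_upper))
  expect_true(curve1$depth_exceeds_census[3])
  expect_false(curve1$depth_exceeds_census[1])

  # on low-diversity samples (few species, large counts) the bootstrap CI
  # at census depth brackets the exact census similarity; high-diversity
  # samples carry a known downward resampling bias instead (singleton
  # species inflate the squared-frequency terms)
  vg <- paste0("IGHV1-", c(2, 8, 18, 46, 69))
  withr::with_seed(55, {
    la <- make_records(rep("ARDYW", 400),
                       v_gene = sample(vg, 400, TRUE, prob = c(5:1) / 15))
    lb <- make_records(rep("ARDYW", 400),
                       v_gene = sample(vg, 400, TRUE, prob = c(1:5) / 15))
  })
  exact <- morisita_horn(species_reduce(la), species_reduce(lb))
  cv <- subsampled_similarity(la, lb, depths = 400, n_boot = 30, seed = 9)
  expect_true(cv$ci_lower <= exact && exact <= cv$ci_upper)

  # disjoint V pools give near-zero similarity at every depth
  d1 <- make_records(rep("ARDYW", 60), v_gene = "IGHV1-2")
  d2 <- make_records(rep("ARDYW", 60), v_gene = "IGHV3-23")
  dis <- subsampled_similarity(d1, d2, depths = c(10, 50), n_boot = 5,
                               seed = 1)
  expect_true(all(dis$mean_ch == 0))
  expect_error(subsampled_similarity(d1, d2, depths = numeric(0)), "empty")
  expect_error(subsampled_similarity(d1, d2, depths = 5), ">= 10")
})

test_that("pairwise similarity matrix is symmetric with unit diagonal", {
  sim <- small_study(seed = 53)
  samples <- split_replicates(sim$records)[1:4]
  m <- pairwise_similarity(samples)
  expect_equal(dim(m), c(4, 4))
  expect_equal(diag(m), stats::setNames(rep(1, 4), names(samples)))
  expect_equal(m, t(m))
  expect_equal(m[1, 2],
               morisita_horn(species_reduce(samples[[1]]),
                             species_reduce(samples[[2]])))
  ident <- pairwise_similarity(list(a = samples[[1]], b = samples[[1]]))
  expect_true(all(ident == 1))
})

test_that("single-linkage clustering matches the exhaustive-merge oracle", {
  withr::with_seed(61, {
    for (i in 1:5) {
      k <- sample(5:8, 1)
      m <- matrix(stats::runif(k * k, 0.2, 1), k)
      m <- (m + t(m)) / 2
      diag(m) <- 1
      dimnames(m) <- list(letters[1:k], letters[1:k])
      tree <- cluster_replicates(m)
      d <- as.matrix(stats::dist(m))
      expect_equal(tree$height, slink_oracle_heights(d), tolerance = 1e-12)
    }
  })
  # block-diagonal similarity: two clean top-level clusters
  bm <- matrix(0.5, 8, 8)
  bm[1:4, 1:4] <- 0.99
  bm[5:8, 5:8] <- 0.99
  diag(bm) <- 1
  dimnames(bm) <- list(paste0("g", 1:8), paste0("g", 1:8))
  tree <- cluster_replicates(bm)
  groups <- stats::cutree(tree, k = 2)
  expect_equal(length(unique(groups[paste0("g", 1:4)])), 1)
  expect_equal(length(unique(groups[paste0("g", 5:8)])), 1)
  expect_false(groups[["g1"]] == groups[["g5"]])

  # identical similarity profiles merge at height zero
  flat <- matrix(0.7, 4, 4); diag(flat) <- 1
  dimnames(flat) <- list(letters[1:4], letters[1:4])
  expect_equal(cluster_replicates(flat, "one_minus_similarity")$height,
               rep(0.3, 3))
  same <- matrix(0.5, 3, 3)
  dimnames(same) <- list(letters[1:3], letters[1:3])
  expect_equal(cluster_replicates(same)$height, rep(0, 2))
  expect_error(cluster_replicates(matrix(1, 2, 3)), "square")
})

test_that("replicates cluster by subject and timepoint", {
  shift <- default_v_gene_pool()
  shift[] <- rev(as.numeric(shift))  # reversed usage ranking at T2
  sim <- simulate_study(sim_config(
    n_subjects = 2, n_timepoints = 2, n_replicates = 6,
    n_lineages = 400, census = TRUE, v_gene_pool_t2 = shift, seed = 71))
  m <- pairwise_similarity(split_replicates(sim$records))
  tree <- cluster_replicates(m)
  cl <- stats::cutree(tree, k = 4)
  truth <- sub("\\.R[0-9]+$", "", names(cl))
  # every subject-timepoint group lands in exactly one cluster
  expect_equal(unname(vapply(split(cl, truth),
                             function(g) length(unique(g)), integer(1))),
               rep(1L, 4))
  expect_equal(length(unique(cl)), 4)
})

test_that("stratified similarity separates isotype-specific timepoint shifts", {
  # memory usage at T2 concentrates on genes that are rare in the base
  # pool, so the IgG-dominated stratum shifts while the naive (IgM) one
  # does not
  shift <- stats::setNames(rep(0.25, 4),
                           c("IGHV1-18", "IGHV1-46", "IGHV2-5", "IGHV6-1"))
  sim <- simulate_study(sim_config(
    n_subjects = 1, n_timepoints = 2, n_replicates = 4,
    n_lineages = 3000, census = TRUE, naive_fraction = 0.6,
    memory_isotype_probs = c(IgM = 0.05, IgG = 0.95),
    memory_overrides = list(v_gene_pool_t2 = shift), seed = 73))
  out <- stratified_similarity(sim$records)
  med <- function(str, cmp) out$median[out$stratum == str &
                                         out$comparison == cmp]
  # only memory (IgG-dominated) usage shifts between timepoints
  expect_lt(med("IgG", "inter"), med("IgM_lt2_mutations", "inter"))
  expect_lt(med("IgG", "inter"), med("IgG", "intra"))

  # exchangeable null: relabel half of one timepoint's replicates as a
  # second timepoint, so intra and inter pairs are statistically identical
  null_sim <- simulate_study(sim_config(
    n_subjects = 1, n_timepoints = 1, n_replicates = 8, n_sequences = 400,
    seed = 79))
  nrec <- null_sim$records
  idx <- as.integer(sub("R", "", nrec$replicate))
  nrec$timepoint <- ifelse(idx <= 4, "T1", "T2")
  nrec$replicate <- paste0("R", ((idx - 1) %% 4) + 1)
  null_out <- stratified_similarity(nrec)
  intra <- null_out[null_out$stratum == "all" &
                      null_out$comparison == "intra", ]
  inter <- null_out[null_out$stratum == "all" &
                      null_out$comparison == "inter", ]
  expect_true(intra$q25 <= inter$q75 && inter$q25 <= intra$q75)
})

test_that("the mutation cut places records on the documented side", {
  recs <- make_records(rep("ARDYW", 40),
                       replicate = rep(c("R1", "R2"), 20),
                       timepoint = rep(c("T1", "T2"), each = 20),
                       isotype = "IgM", v_mutation_count = 1L)
  out <- stratified_similarity(recs, min_records = 5)
  # v_mutation_count = 1 is "fewer than two": only that stratum has pairs
  expect_gt(out$n_pairs[out$stratum == "IgM_lt2_mutations" &
                          out$comparison == "intra"], 0)
  expect_equal(sum(out$n_pairs[out$stratum == "IgM_ge2_mutations"]), 0)
  expect_equal(sum(out$n_pairs[out$stratum == "IgG"]), 0)
  expect_true(all(is.na(out$median[out$stratum == "IgG"])))
})
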