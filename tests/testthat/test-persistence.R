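test_that("turnover and persistence match hand computation", {
  # t1 {a..h}, t2 {d..k}: appearing 3, disappearing 3, total 11
  rep_ <- persistence_report(letters[1:8], letters[4:11])
  expect_equal(rep_$n_appearing, 3)
  expect_equal(rep_$n_disappearing, 3)
  expect_equal(rep_$n_shared, 5)
  expect_equal(rep_$n_total, 11)
  expect_equal(rep_$turnover_pct, 600 / 11)
  expect_equal(rep_$persistence_pct, 100 - 600 / 11)

  expect_equal(persistence_report(letters[1:5], letters[1:5])$persistence_pct,
               100)
  expect_equal(persistence_report(letters[1:5], letters[6:9])$persistence_pct,
               0)
  expect_error(persistence_report(character(0), letters[1:3]), "nonempty")
})

test_that("persistence identities hold on random set pairs", {
  withr::with_seed(211, {
    for (i in 1:300) {
      universe <- seq_len(sample(5:60, 1))
      s1 <- as.character(sample(universe, sample(seq_along(universe), 1)))
      s2 <- as.character(sample(universe, sample(seq_along(universe), 1)))
      r <- persistence_report(s1, s2)
      expect_equal(r$n_appearing + r$n_disappearing + r$n_shared, r$n_total)
      expect_equal(r$persistence_pct + r$turnover_pct, 100)
      expect_equal(r$persistence_pct, 100 * r$n_shared / r$n_total)
      expect_true(r$persistence_pct >= 0 && r$persistence_pct <= 100)
    }
  })
})

test_that("persistence is consistent with shared_clonotypes and refines by level", {
  for (seed in c(221, 223)) {
    sim <- small_study(seed = seed)
    for (s in c("S1", "S2")) {
      r1 <- sim$records[sim$records$subject == s &
                          sim$records$timepoint == "T1", ]
      r2 <- sim$records[sim$records$subject == s &
                          sim$records$timepoint == "T2", ]
      rc <- persistence_report(r1, r2, level = "clonotype")
      rs <- persistence_report(r1, r2, level = "sequence")
      # nucleotide identity refines clonotype identity
      expect_lte(rs$persistence_pct, rc$persistence_pct)
      # cross-module consistency with the set algebra
      sets <- shared_clonotypes(collapse_clonotypes(r1),
                                collapse_clonotypes(r2))
      expect_equal(rc$n_shared, length(sets$shared))
      expect_equal(rc$n_total, length(sets$shared) + length(sets$only_a) +
                     length(sets$only_b))
    }
  }
})

test_that("census sampling recovers the configured persistent fraction", {
  p <- 0.5
  shared_frac <- vapply(1:5, function(seed) {
    sim <- simulate_study(sim_config(
      n_subjects = 1, n_timepoints = 2, n_replicates = 2,
      n_lineages = 800, census = TRUE, persistent_fraction = p,
      public_pool_weight = 0, seed = 300 + seed))
    r1 <- sim$records[sim$records$timepoint == "T1", ]
    r2 <- sim$records[sim$records$timepoint == "T2", ]
    rep_ <- persistence_report(r1, r2)
    rep_$n_shared / rep_$n_t1
  }, numeric(1))
  n <- 5 * 800
  expect_lt(abs(mean(shared_frac) - p), 1.96 * sqrt(p * (1 - p) / n) + 0.01)
})

test_that("observed sharing grows with sampling depth", {
  sim <- simulate_study(sim_config(
    n_subjects = 1, n_timepoints = 2, n_replicates = 3,
    n_lineages = 2000, census = TRUE, persistent_fraction = 0.3,
    public_pool_weight = 0, seed = 401))
  r1 <- sim$records[sim$records$timepoint == "T1", ]
  r2 <- sim$records[sim$records$timepoint == "T2", ]
  curve <- sharing_vs_depth(r1, r2, depths = c(10, 100, 1000), n_boot = 20,
                            seed = 5)
  expect_true(all(diff(curve$mean_shared_fraction) > 0))
  expect_gt(curve$mean_shared_fraction[curve$depth == 1000],
            curve$mean_shared_fraction[curve$depth == 10])
  same <- sharing_vs_depth(r1, r1, depths = 5 * nrow(r1), n_boot = 10,
                           seed = 6)
  expect_gt(same$mean_shared_fraction, 0.9)
  # determinism
  expect_identical(curve, sharing_vs_depth(r1, r2, depths = c(10, 100, 1000),
                                           n_boot = 20, seed = 5))
})

test_that("logo matrices are per-position frequencies", {
  one <- logo_matrix("ARDYYYYYGMDVW", 13)
  expect_equal(dim(one), c(20, 13))
  expect_true(all(colSums(one) == 1))
  expect_true(all(one %in% c(0, 1)))
  expect_equal(one["A", 1], 1)

  two <- logo_matrix(c("ARDYW", "ARDYF"), 5)
  expect_equal(sort(two[, 5][two[, 5] > 0]), c(W = 0.5, F = 0.5)[c("F", "W")])
  expect_true(all(two[, 1:4] %in% c(0, 1)))

  withr::with_seed(431, {
    aa <- rownames(one)
    rand <- vapply(1:4000, function(i)
      paste0(sample(aa, 9, replace = TRUE), collapse = ""), "")
    lm <- logo_matrix(rand, 9)
    se <- sqrt(0.05 * 0.95 / 4000)
    expect_true(all(abs(lm - 0.05) <= 4 * se))
  })
  expect_error(logo_matrix(c("AAA", "CCCC"), 5), "no CDRH3")
})

test_that("memory-biased persistence shapes the shared-clonotype group", {
  short <- default_cdrh3_length_distribution(mean = 12, sd = 2.5)
  sim <- simulate_study(sim_config(
    n_subjects = 1, n_timepoints = 2, n_replicates = 4,
    n_lineages = 2500, census = TRUE,
    naive_fraction = 0.7, persistent_fraction = 0.02,
    memory_overrides = list(persistent_fraction = 0.5,
                            lineage_size_exponent = 2.0,
                            cdrh3_length_distribution = short),
    public_pool_weight = 0, seed = 443))
  r1 <- sim$records[sim$records$timepoint == "T1", ]
  r2 <- sim$records[sim$records$timepoint == "T2", ]
  ch <- characterize_persistent(r1, r2)
  g <- function(metric, col) ch$tests[[col]][ch$tests$metric == metric]
  expect_gt(g("igg_frequency", "mean_shared"),
            g("igg_frequency", "mean_unshared"))
  expect_gt(g("mean_v_mutations", "mean_shared"),
            g("mean_v_mutations", "mean_unshared"))
  expect_gt(g("multi_replicate", "mean_shared"),
            g("multi_replicate", "mean_unshared"))
  expect_lt(g("cdrh3_length", "mean_shared"),
            g("cdrh3_length", "mean_unshared"))
  expect_equal(sum(table(ch$clonotypes$group)), nrow(ch$clonotypes))
  expect_true(all(abs(colSums(ch$logos$shared) - 1) < 1e-9))

  # null control: identical generative parameters for persistent and
  # transient lineages leave the groups indistinguishable
  null_sim <- simulate_study(sim_config(
    n_subjects = 1, n_timepoints = 2, n_replicates = 4,
    n_lineages = 2000, census = TRUE, persistent_fraction = 0.3,
    public_pool_weight = 0, seed = 449))
  n1 <- null_sim$records[null_sim$records$timepoint == "T1", ]
  n2 <- null_sim$records[null_sim$records$timepoint == "T2", ]
  nch <- characterize_persistent(n1, n2)
  # multi-replicate occurrence is excluded: shared clonotypes get two
  # timepoints' worth of chances to recur, a structural sampling bias that
  # exists even under the null (see the methods vignette)
  unbiased <- nch$tests$metric != "multi_replicate"
  expect_true(all(nch$tests$p_adjusted[unbiased] > 0.001, na.rm = TRUE))
})

test_that("persistent public clonotypes are recovered from ground truth", {
  sim <- simulate_study(sim_config(
    n_subjects = 2, n_timepoints = 2, n_replicates = 2,
    n_lineages = 1500, census = TRUE,
    public_pool_size = 40, public_pool_weight = 0.05,
    persistent_fraction = 0.05,
    public_overrides = list(persistent_fraction = 1),
    seed = 457))
  pp <- persistent_public(sim$records)
  reg <- sim$truth$lineages
  reg$key <- paste(reg$v_gene, reg$j_gene,
                   substr(reg$junction_aa, 2, nchar(reg$junction_aa) - 1),
                   sep = "|")
  # public lineages persist with probability 1: every clonotype that is
  # public (sampled in both subjects) must be persistent-public
  s1_pub <- unique(reg$key[reg$public & reg$subject == "S1"])
  s2_pub <- unique(reg$key[reg$public & reg$subject == "S2"])
  truly_public <- intersect(s1_pub, s2_pub)
  expect_gt(length(pp$persistent_public), 0)
  expect_true(all(pp$persistent_public %in% truly_public))
  expect_true(all(pp$persistent_public %in% pp$public))
  # any_subject mode is a superset of all_subjects mode
  pp_any <- persistent_public(sim$records, mode = "any_subject")
  expect_true(all(pp$persistent_public %in% pp_any$persistent_public))

  # without a public pool the persistent-public set is empty
  nop <- simulate_study(sim_config(
    n_subjects = 2, n_timepoints = 2, n_replicates = 2,
    n_lineages = 800, census = TRUE, public_pool_weight = 0, seed = 461))
  expect_length(persistent_public(nop$records)$persistent_public, 0)
  expect_error(persistent_public(sim$records[sim$records$subject == "S1", ]),
               "2 subjects")
})

test_that("public clonotypes configured with short CDRH3s shift the length distribution", {
  short <- default_cdrh3_length_distribution(mean = 9, sd = 1.5)
  sim <- simulate_study(sim_config(
    n_subjects = 2, n_timepoints = 2, n_replicates = 2,
    n_lineages = 1500, census = TRUE,
    public_pool_size = 60, public_pool_weight = 0.05,
    persistent_fraction = 0.05,
    public_overrides = list(persistent_fraction = 1,
                            cdrh3_length_distribution = short),
    seed = 467))
  r <- sim$records
  pub_keys <- persistent_public(r)$persistent_public
  all_keys <- unique(clonotype_key(r))
  key_len <- nchar(sub("^[^|]+\\|[^|]+\\|", "", all_keys))
  expect_lt(stats::median(key_len[all_keys %in% pub_keys]),
            stats::median(key_len[!all_keys %in% pub_keys]))
})
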