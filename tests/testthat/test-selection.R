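# Hierarchical F-statistics, AMOVA, the island-model null and outlier
# classification.

test_that("locus F-statistics hit the no- and full-differentiation limits", {
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 50)
  grps <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  # same allele frequency everywhere -> no differentiation
  set.seed(11)
  flat <- matrix(rbinom(200, 2, 0.4), 1, 200)
  g_flat <- toy_genotypes(flat, pops, grps)
  expect_lte(abs(locus_fstats(g_flat, "L001")$f_ct), 0.02)
  # groups fixed for alternative alleles -> complete differentiation
  fixed <- matrix(rep(c(0L, 2L), each = 100), 1, 200)
  g_fix <- toy_genotypes(fixed, pops, grps)
  fs <- locus_fstats(g_fix, "L001")
  expect_gte(fs$f_ct, 0.98)
  expect_gte(fs$f_st, 0.98)
})

test_that("monomorphic loci are flagged with undefined indices", {
  g <- toy_genotypes(matrix(0L, 1, 8), rep(c("p1", "p2"), each = 4),
                     c(p1 = "g1", p2 = "g2"))
  fs <- locus_fstats(g, "L001")
  expect_true(fs$monomorphic)
  expect_true(is.na(fs$f_ct))
})

test_that("variance components equal the brute-force nested ANOVA", {
  # printed toy: 2 groups x 2 pops x 4 diploids
  dosage <- c(2, 2, 1, 2,  1, 2, 2, 1,  0, 1, 0, 0,  1, 0, 0, 0)
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 4)
  grps <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  g <- toy_genotypes(matrix(dosage, 1), pops, grps)
  mine <- locus_fstats(g, "L001")
  oracle <- oracle_fstats(dosage, pops, grps)
  expect_equal(mine$f_ct, oracle$f_ct, tolerance = 1e-10)
  expect_equal(mine$f_sc, oracle$f_sc, tolerance = 1e-10)
  expect_equal(mine$f_st, oracle$f_st, tolerance = 1e-10)
})

test_that("F-statistics match the brute-force oracle on random toys", {
  set.seed(202)
  for (i in 1:100) {
    toy <- random_fstats_toy()
    g <- toy_genotypes(matrix(toy$dosage, 1), toy$pop_of_ind,
                       toy$grp_of_pop)
    mine <- locus_fstats(g, "L001")
    oracle <- oracle_fstats(toy$dosage, toy$pop_of_ind, toy$grp_of_pop)
    expect_equal(mine$f_ct, oracle$f_ct, tolerance = 1e-10)
    expect_equal(mine$f_sc, oracle$f_sc, tolerance = 1e-10)
    expect_equal(mine$f_st, oracle$f_st, tolerance = 1e-10)
  }
})

test_that("AMOVA percentages sum to 100 and p-values are proper", {
  sim <- simulate_hierarchical_island_dataset(
    groups = 2, demes_per_group = 8, m_within = 8, m_among = 0.3,
    n_loci = 150, diploids_per_deme = 6, seed = 31)
  am <- amova_three_level(sim$genotypes, n_permutations = 49, seed = 5)
  expect_equal(sum(am$percentages), 100, tolerance = 1e-9)
  expect_true(all(am$p_values >= 1 / 50 & am$p_values <= 1))
  expect_gt(am$f_stats["f_ct"], 0)
})

test_that("single-locus AMOVA agrees with locus_fstats", {
  toy <- within(list(), {
    dosage <- c(2, 1, 1, 2, 0, 1, 0, 0, 1, 1, 2, 0)
    pops <- rep(c("p1", "p2", "p3"), each = 4)
    grps <- c(p1 = "g1", p2 = "g1", p3 = "g2")
  })
  # need >= 2 pops per group for the permutation design; add one pop
  dosage <- c(toy$dosage, c(0, 0, 1, 0))
  pops <- c(toy$pops, rep("p4", 4))
  grps <- c(toy$grps, p4 = "g2")
  g <- toy_genotypes(matrix(dosage, 1), pops, grps)
  am <- amova_three_level(g, n_permutations = 9, seed = 2)
  fs <- locus_fstats(g, "L001")
  expect_equal(unname(am$f_stats["f_ct"]), fs$f_ct, tolerance = 1e-12)
  expect_equal(unname(am$f_stats["f_sc"]), fs$f_sc, tolerance = 1e-12)
  expect_equal(unname(am$f_stats["f_st"]), fs$f_st, tolerance = 1e-12)
})

test_that("AMOVA keeps its nominal size on panmictic data", {
  # exact null: all individuals drawn from the same allele frequencies
  reject <- matrix(NA, 20, 3)
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 5)
  grps <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  set.seed(404)
  for (r in 1:20) {
    freq <- runif(120, 0.1, 0.9)
    dosage <- matrix(rbinom(120 * 20, 2, freq), 120, 20)
    g <- toy_genotypes(dosage, pops, grps)
    am <- amova_three_level(g, n_permutations = 39, seed = 500 + r)
    reject[r, ] <- am$p_values <= 0.05
  }
  expect_gte(mean(rowSums(reject) == 0), 0.9)
})

test_that("the island-model panmixia and hierarchy limits behave", {
  pan <- simulate_hierarchical_island_dataset(
    groups = 2, demes_per_group = 6, m_within = 800, m_among = 800,
    n_loci = 800, diploids_per_deme = 8, seed = 61)
  fs <- locus_fstats_all(pan$genotypes)
  mono <- fs$monomorphic
  expect_lte(abs(mean(fs$f_ct[!mono])), 0.02)
  hier <- simulate_hierarchical_island_dataset(
    groups = 2, demes_per_group = 6, m_within = 50, m_among = 0.2,
    n_loci = 800, diploids_per_deme = 8, seed = 62)
  fh <- locus_fstats_all(hier$genotypes)
  expect_gt(mean(fh$f_ct, na.rm = TRUE), mean(fh$f_sc, na.rm = TRUE))
})

test_that("null simulation returns the requested loci with sane ranges", {
  nf <- simulate_null_fdist(400, groups = 2, demes_per_group = 6,
                            target_f_ct = 0.2, target_f_sc = 0.1,
                            seed = 71, n_calibration = 300)
  expect_equal(nrow(nf$table), 400L)
  expect_true(all(nf$table$f_ct <= 1, na.rm = TRUE))
  expect_true(all(nf$table$heterozygosity >= 0 &
                    nf$table$heterozygosity <= 1))
})

test_that("outlier classification flags extremes and degenerate alpha", {
  set.seed(9)
  sim_tab <- data.frame(locus = sprintf("s%04d", 1:4000),
                        heterozygosity = runif(4000, 0.05, 0.5),
                        f_ct = rbeta(4000, 2, 8),
                        f_sc = 0.1, f_st = 0.2)
  env <- null_envelope(sim_tab, n_bins = 10, alpha = 0.01)
  obs <- data.frame(locus = c("hi", "lo", "mid"),
                    heterozygosity = c(0.2, 0.2, 0.2),
                    f_ct = c(0.999, 1e-6, median(sim_tab$f_ct)),
                    f_sc = 0.1, f_st = 0.2)
  cls <- classify_outliers(obs, env, alpha = 0.01)
  expect_equal(cls$class, c("divergent", "balancing", "neutral"))
  expect_lte(cls$p[1], 1 / 400)   # above every simulated value in bin
  # alpha = 1: everything off the bin median is flagged
  env1 <- null_envelope(sim_tab, n_bins = 10, alpha = 1)
  cls1 <- classify_outliers(obs[1:2, ], env1, alpha = 1)
  expect_true(all(cls1$class != "neutral"))
  # mismatched significance is refused
  expect_error(classify_outliers(obs, env, alpha = 0.05), "different")
})

test_that("envelope quantiles are monotone in alpha", {
  set.seed(12)
  sim_tab <- data.frame(locus = sprintf("s%04d", 1:3000),
                        heterozygosity = runif(3000, 0.05, 0.5),
                        f_ct = rbeta(3000, 2, 8),
                        f_sc = 0.1, f_st = 0.2)
  e01 <- null_envelope(sim_tab, n_bins = 8, alpha = 0.01)
  e10 <- null_envelope(sim_tab, n_bins = 8, alpha = 0.10)
  expect_true(all(e01$upper >= e10$upper))
  expect_true(all(e01$lower <= e10$lower))
})
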