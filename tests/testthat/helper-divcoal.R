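# Shared fixture builders and independent oracles.

# Minimal genotype_matrix from a dosage matrix (sites x individuals).
toy_genotypes <- function(dosage, pop_of_ind, group_of_pop,
                          locus = NULL, ancestral = "unknown") {
  dosage <- as.matrix(dosage)
  n_s <- nrow(dosage)
  if (is.null(locus)) locus <- sprintf("L%03d", seq_len(n_s))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("i%03d", seq_len(ncol(dosage)))
  sites <- data.frame(locus = locus,
                      id = sprintf("%s_s", locus), pos = seq_len(n_s),
                      ref = "A", alt = "T",
                      ancestral = rep_len(ancestral, n_s),
                      stringsAsFactors = FALSE)
  pop <- setNames(pop_of_ind, colnames(dosage))
  genotype_matrix(dosage, sites, pop[!is.na(pop)], group_of_pop)
}

# Brute-force three-level nested ANOVA on allele copies, computed with
# explicit loops over groups/pops/copies (independent of the package's
# vectorized counts-based algebra).  dosage: per-individual {0,1,2,NA};
# each called individual contributes two allele copies.
oracle_fstats <- function(dosage, pop_of_ind, group_of_pop) {
  x <- c(); pop <- c()
  for (i in seq_along(dosage)) {
    if (is.na(dosage[i])) next
    copies <- switch(as.character(dosage[i]),
                     "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
    x <- c(x, copies); pop <- c(pop, rep(pop_of_ind[i], 2))
  }
  grp <- unname(group_of_pop[pop])
  pops <- unique(pop); grps <- unique(grp)
  N <- length(x); P <- length(pops); G <- length(grps)
  xbar <- mean(x)
  ss_w <- 0; ss_b <- 0; ss_a <- 0
  np <- c(); ng <- c()
  for (gr in grps) {
    xg <- x[grp == gr]
    ng[gr] <- length(xg)
    ss_a <- ss_a + length(xg) * (mean(xg) - xbar)^2
    for (p in unique(pop[grp == gr])) {
      xp <- x[pop == p]
      np[p] <- length(xp)
      ss_b <- ss_b + length(xp) * (mean(xp) - mean(xg))^2
      ss_w <- ss_w + sum((xp - mean(xp))^2)
    }
  }
  grp_of_pop <- unname(group_of_pop[pops])
  sum_np2_over_ng <- 0
  for (j in seq_along(pops))
    sum_np2_over_ng <- sum_np2_over_ng +
      np[pops[j]]^2 / ng[grp_of_pop[j]]
  n1 <- (N - sum_np2_over_ng) / (P - G)
  n2 <- (sum_np2_over_ng - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(ng^2) / N) / (G - 1)
  ms_c <- ss_w / (N - P)
  ms_b <- ss_b / (P - G)
  ms_a <- ss_a / (G - 1)
  sc <- ms_c
  sb <- (ms_b - sc) / n1
  sa <- (ms_a - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  list(sigma = unname(c(sa, sb, sc)),
       f_ct = unname(sa / tot), f_sc = unname(sb / (sb + sc)),
       f_st = unname((sa + sb) / tot))
}

# Random small hierarchical toy for the property tests.
random_fstats_toy <- function() {
  n_pops <- sample(4:6, 1)
  grp_of_pop <- setNames(sample(c("g1", "g2"), n_pops, replace = TRUE),
                         sprintf("p%d", seq_len(n_pops)))
  while (length(unique(grp_of_pop)) < 2)
    grp_of_pop[] <- sample(c("g1", "g2"), n_pops, replace = TRUE)
  sizes <- sample(3:8, n_pops, replace = TRUE)
  pop_of_ind <- rep(names(grp_of_pop), sizes)
  n <- length(pop_of_ind)
  repeat {
    freq_by_pop <- runif(n_pops)
    dosage <- rbinom(n, 2, freq_by_pop[match(pop_of_ind,
                                             names(grp_of_pop))])
    if (sum(dosage) > 0 && sum(dosage) < 2 * n) break
  }
  list(dosage = dosage, pop_of_ind = pop_of_ind, grp_of_pop = grp_of_pop)
}

# Forward WF oracle spectrum for a (single-class) divergence model.
forward_wf_oracle <- function(p, n1, n2, theta = 2e4, N_anc = 400L,
                              seed = 1L) {
  forward_wf_jafs(p[["nu1"]], p[["nu2"]], forward_phases(p), n1, n2,
                  theta = theta, N_anc = N_anc, seed = seed)
}

expect_jafs_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_identical(a$mask, b$mask)
}
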