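# Hierarchical F-statistics from nested analysis of molecular variance on
# allele-indicator variables, the coalescent null distribution under a
# hierarchical island model, and FCT outlier classification.

# Per-population alt-copy counts A and called-copy counts C for every site.
pop_allele_counts <- function(g) {
  pops <- unique(unname(g$pop))
  inds <- names(g$pop)
  d <- g$geno[, inds, drop = FALSE]
  Z <- outer(unname(g$pop), pops, `==`) * 1
  dd <- d; dd[is.na(dd)] <- 0L
  A <- dd %*% Z
  C <- 2 * ((!is.na(d)) %*% Z)
  colnames(A) <- colnames(C) <- pops
  list(A = A, C = C, pops = pops,
       pop_group = unname(g$groups[pops]))
}

# Variance components of the three-level nested ANOVA, vectorized over
# sites.  A, C: sites x pops matrices of alt copies / called copies;
# pop_group: group id per pop column.  Unequal sample sizes enter through
# the standard expected-mean-square coefficients.
amova_components <- function(A, C, pop_group) {
  grp <- unique(pop_group)
  Gm <- outer(pop_group, grp, `==`) * 1
  Ag <- A %*% Gm; Cg <- C %*% Gm
  N <- rowSums(C); D <- rowSums(A)
  safe_div <- function(x, y) ifelse(y > 0, x / ifelse(y > 0, y, 1), 0)
  sum_p <- rowSums(safe_div(A^2, C))      # sum_p A_p^2 / C_p
  sum_g <- rowSums(safe_div(Ag^2, Cg))    # sum_g A_g^2 / C_g
  ss_w <- D - sum_p
  ss_b <- sum_p - sum_g
  ss_a <- sum_g - D^2 / N
  P_eff <- rowSums(C > 0); G_eff <- rowSums(Cg > 0)
  df_c <- N - P_eff; df_b <- P_eff - G_eff; df_a <- G_eff - 1
  # EMS coefficients for unequal sizes
  cc_over_g <- rowSums(safe_div(C^2, Cg[, match(pop_group, grp),
                                       drop = FALSE]))
  n1 <- (N - cc_over_g) / df_b
  n2 <- (cc_over_g - rowSums(C^2) / N) / df_a
  n3 <- (N - rowSums(Cg^2) / N) / df_a
  sc <- ss_w / df_c
  sb <- (ss_b / df_b - sc) / n1
  sa <- (ss_a / df_a - sc - n2 * sb) / n3
  cbind(sigma_a = sa, sigma_b = sb, sigma_c = sc)
}

fstats_from_components <- function(comp) {
  tot <- rowSums(comp)
  data.frame(
    f_ct = comp[, "sigma_a"] / tot,
    f_sc = comp[, "sigma_b"] / (comp[, "sigma_b"] + comp[, "sigma_c"]),
    f_st = (comp[, "sigma_a"] + comp[, "sigma_b"]) / tot)
}

# Mean unbiased within-population gene diversity over populations.
mean_gene_diversity <- function(A, C) {
  p <- ifelse(C > 0, A / ifelse(C > 0, C, 1), NA)
  h <- C / pmax(C - 1, 1) * 2 * p * (1 - p)
  h[C < 2] <- NA
  rowMeans(h, na.rm = TRUE)
}

#' Hierarchical F-statistics of a single locus
#'
#' Variance components from a three-level nested ANOVA on allele
#' indicators (among groups, among populations within groups, within
#' populations), with unequal sample sizes handled through the standard
#' expected-mean-square coefficients.  `F_CT = sigma2_a / sigma2_total`,
#' `F_SC = sigma2_b / (sigma2_b + sigma2_c)`,
#' `F_ST = (sigma2_a + sigma2_b) / sigma2_total`.
#'
#' @param g a [genotype_matrix()] with at least 2 populations in at
#'   least 2 groups.
#' @param locus locus id (all its sites are averaged; with one SNP per
#'   locus this is a single site).
#' @return A one-row data.frame `locus`, `heterozygosity`, `f_ct`,
#'   `f_sc`, `f_st`, `monomorphic`.  F-statistics of a monomorphic locus
#'   are `NA` with `monomorphic = TRUE`.
#' @export
locus_fstats <- function(g, locus) {
  keep <- g$sites$locus == locus
  if (!any(keep)) stop("unknown locus: ", locus)
  tab <- locus_fstats_all(subset_sites(g, keep))
  out <- data.frame(locus = locus,
                    heterozygosity = mean(tab$heterozygosity),
                    f_ct = mean(tab$f_ct), f_sc = mean(tab$f_sc),
                    f_st = mean(tab$f_st),
                    monomorphic = all(tab$monomorphic))
  rownames(out) <- NULL
  out
}

#' Per-site hierarchical F-statistics for all loci
#'
#' Vectorized version of [locus_fstats()]: one row per site.
#'
#' @param g a [genotype_matrix()].
#' @return A data.frame with one row per site: `locus`, `site`,
#'   `heterozygosity`, `f_ct`, `f_sc`, `f_st`, `monomorphic`.
#' @export
locus_fstats_all <- function(g) {
  pc <- pop_allele_counts(g)
  if (length(pc$pops) < 2 || length(unique(pc$pop_group)) < 2)
    stop("need >= 2 populations in >= 2 groups")
  comp <- amova_components(pc$A, pc$C, pc$pop_group)
  fs <- fstats_from_components(comp)
  D <- rowSums(pc$A); N <- rowSums(pc$C)
  mono <- D == 0 | D == N
  fs[mono, ] <- NA
  data.frame(locus = g$sites$locus, site = g$sites$id,
             heterozygosity = mean_gene_diversity(pc$A, pc$C),
             fs, monomorphic = mono, row.names = NULL)
}

#' Three-level analysis of molecular variance with permutation tests
#'
#' Partitions genetic variance among groups (species), among populations
#' within groups, and within populations, summing variance components
#' over loci.  Permutation p-values: `F_CT` permutes whole populations
#' among groups; `F_SC` permutes individuals among populations within
#' their group; `F_ST` permutes individuals among all populations.
#' `p = (count >= observed + 1) / (B + 1)`.
#'
#' @param g a [genotype_matrix()].
#' @param n_permutations number of permutations `B`.
#' @param seed integer seed.
#' @return A list of class `amova` with `components`, `percentages`
#'   (summing to 100), `f_stats` and `p_values`.
#' @export
amova_three_level <- function(g, n_permutations = 99L, seed = 1L) {
  pc <- pop_allele_counts(g)
  comp_tot <- function(A, C, pop_group) {
    comp <- amova_components(A, C, pop_group)
    colSums(comp, na.rm = TRUE)
  }
  obs_comp <- comp_tot(pc$A, pc$C, pc$pop_group)
  tot <- sum(obs_comp)
  fs <- c(f_ct = unname(obs_comp["sigma_a"] / tot),
          f_sc = unname(obs_comp["sigma_b"] /
                          (obs_comp["sigma_b"] + obs_comp["sigma_c"])),
          f_st = unname((obs_comp["sigma_a"] + obs_comp["sigma_b"]) / tot))
  d <- g$geno[, names(g$pop), drop = FALSE]
  pops <- pc$pops
  counts_for <- function(pop_of_ind) {
    Z <- outer(pop_of_ind, pops, `==`) * 1
    dd <- d; dd[is.na(dd)] <- 0L
    list(A = dd %*% Z, C = 2 * ((!is.na(d)) %*% Z))
  }
  pv <- with_seed(seed, {
    ge_ct <- ge_sc <- ge_st <- 0L
    pop_of_ind <- unname(g$pop)
    grp_of_ind <- unname(g$groups[pop_of_ind])
    for (b in seq_len(n_permutations)) {
      # (a) pops among groups
      pg <- sample(pc$pop_group)
      cs <- comp_tot(pc$A, pc$C, pg)
      if (cs["sigma_a"] / sum(cs) >= fs["f_ct"]) ge_ct <- ge_ct + 1L
      # (b) individuals among pops within groups
      pop_b <- pop_of_ind
      for (gr in unique(grp_of_ind)) {
        i <- which(grp_of_ind == gr)
        pop_b[i] <- pop_b[i][sample(length(i))]
      }
      cb <- counts_for(pop_b)
      csb <- comp_tot(cb$A, cb$C, pc$pop_group)
      if (csb["sigma_b"] / (csb["sigma_b"] + csb["sigma_c"]) >= fs["f_sc"])
        ge_sc <- ge_sc + 1L
      # (c) individuals among all populations
      pop_c <- pop_of_ind[sample(length(pop_of_ind))]
      cc <- counts_for(pop_c)
      csc <- comp_tot(cc$A, cc$C, pc$pop_group)
      if ((csc["sigma_a"] + csc["sigma_b"]) / sum(csc) >= fs["f_st"])
        ge_st <- ge_st + 1L
    }
    c(f_ct = (ge_ct + 1) / (n_permutations + 1),
      f_sc = (ge_sc + 1) / (n_permutations + 1),
      f_st = (ge_st + 1) / (n_permutations + 1))
  })
  structure(list(components = obs_comp,
                 percentages = 100 * obs_comp / tot,
                 f_stats = fs, p_values = pv,
                 n_permutations = n_permutations),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("Three-level AMOVA\n")
  tab <- data.frame(
    source = c("among groups", "among populations within groups",
               "within populations"),
    sigma2 = as.numeric(x$components),
    percent = as.numeric(x$percentages))
  print(tab, row.names = FALSE)
  cat(sprintf("F_CT = %.4f (p = %.4g), F_SC = %.4f (p = %.4g), F_ST = %.4f (p = %.4g)\n",
              x$f_stats["f_ct"], x$p_values["f_ct"],
              x$f_stats["f_sc"], x$p_values["f_sc"],
              x$f_stats["f_st"], x$p_values["f_st"]))
  invisible(x)
}

#' Default sampled design for the island-model null
#'
#' @param groups number of groups sampled.
#' @param demes_sampled demes sampled per group.
#' @param diploids diploid individuals per sampled deme.
#' @return A data.frame with columns `group`, `deme`, `diploids`.
#' @export
island_sample_config <- function(groups = 2L, demes_sampled = 3L,
                                 diploids = 10L) {
  expand.grid(group = seq_len(groups), deme = seq_len(demes_sampled),
              diploids = diploids)[, c("group", "deme", "diploids")]
}

# Simulate n_loci one-SNP loci under a hierarchical island scenario and
# return per-locus F-statistics (plus the diploid dosage matrix).
island_locus_table <- function(n_loci, groups, demes_per_group, m_within,
                               m_among, sample_config, seed) {
  scen <- island_scenario(groups, demes_per_group, m_within, m_among)
  sample_demes <- integer(0)
  pop_of_copy <- character(0)
  for (r in seq_len(nrow(sample_config))) {
    deme0 <- (sample_config$group[r] - 1L) * demes_per_group +
      (sample_config$deme[r] - 1L)
    ncopy <- 2L * sample_config$diploids[r]
    sample_demes <- c(sample_demes, rep(deme0, ncopy))
    pop_of_copy <- c(pop_of_copy,
                     rep(sprintf("G%dD%d", sample_config$group[r],
                                 sample_config$deme[r]), ncopy))
  }
  hap <- with_seed(seed,
    .coal_sim_snps_cpp(as.integer(sample_demes), epochs_for_engine(scen),
                       as.integer(n_loci)))
  odd <- seq(1L, length(sample_demes), by = 2L)
  dos <- hap[, odd, drop = FALSE] + hap[, odd + 1L, drop = FALSE]
  pop_of_ind <- pop_of_copy[odd]
  pops <- unique(pop_of_ind)
  Z <- outer(pop_of_ind, pops, `==`) * 1
  A <- dos %*% Z
  C <- matrix(2 * colSums(Z), n_loci, length(pops), byrow = TRUE)
  pop_group <- sub("D.*", "", pops)
  comp <- amova_components(A, C, pop_group)
  fs <- fstats_from_components(comp)
  list(table = data.frame(locus = sprintf("sim%06d", seq_len(n_loci)),
                          heterozygosity = mean_gene_diversity(A, C),
                          fs, row.names = NULL),
       components = comp, dosage = dos, pop_of_ind = pop_of_ind)
}

multilocus_f <- function(comp) {
  s <- colSums(comp, na.rm = TRUE)
  c(f_ct = unname(s["sigma_a"] / sum(s)),
    f_sc = unname(s["sigma_b"] / (s["sigma_b"] + s["sigma_c"])))
}

#' Simulate the coalescent null distribution of hierarchical F-statistics
#'
#' Calibrates the among-group and within-group scaled migration rates of
#' a hierarchical island model by bisection so that the multilocus mean
#' `F_CT` and `F_SC` of simulated data match the observed targets within
#' 0.01, then simulates `n_loci` independent loci (structured coalescent,
#' one mutation placed uniformly on each genealogy) and returns their
#' per-locus statistics on the sampled configuration.
#'
#' @param n_loci number of null loci to simulate.
#' @param groups,demes_per_group island-model dimensions.
#' @param sample_config sampled design, see [island_sample_config()].
#' @param target_f_ct,target_f_sc multilocus targets in (0, 1).
#' @param seed integer seed.
#' @param n_calibration loci per calibration evaluation.
#' @return A list of class `null_fdist` with the simulated locus `table`
#'   (`locus`, `heterozygosity`, `f_ct`, `f_sc`, `f_st`), the calibrated
#'   rates `m_within`/`m_among`, and the achieved multilocus values.
#' @export
simulate_null_fdist <- function(n_loci, groups = 2L, demes_per_group = 10L,
                                sample_config = island_sample_config(groups),
                                target_f_ct, target_f_sc, seed = 1L,
                                n_calibration = 2000L) {
  stopifnot(n_loci >= 1, target_f_ct > 0, target_f_ct < 1,
            target_f_sc > 0, target_f_sc < 1)
  cal_seed <- derive_seed(seed, 1L)
  eval_f <- function(m_w, m_a, n = n_calibration) {
    sim <- island_locus_table(n, groups, demes_per_group, m_w, m_a,
                              sample_config, cal_seed)
    multilocus_f(sim$components)
  }
  bisect <- function(f, lo, hi, target, steps) {
    # f decreasing in the rate; search on log scale
    for (i in seq_len(steps)) {
      mid <- sqrt(lo * hi)
      if (f(mid) > target) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  m_a <- 1; m_w <- 10
  cal_n <- c(1L, 2L, 5L) * n_calibration
  cal_steps <- c(12L, 12L, 14L)
  for (cycle in 1:3) {
    m_a <- bisect(function(m) eval_f(m_w, m, cal_n[cycle])[["f_ct"]],
                  0.005, 500, target_f_ct, cal_steps[cycle])
    m_w <- bisect(function(m) eval_f(m, m_a, cal_n[cycle])[["f_sc"]],
                  0.005, 500, target_f_sc, cal_steps[cycle])
  }
  sim <- island_locus_table(n_loci, groups, demes_per_group, m_w, m_a,
                            sample_config, derive_seed(seed, 2L))
  achieved <- multilocus_f(sim$components)
  if (abs(achieved[["f_ct"]] - target_f_ct) > 0.02 ||
      abs(achieved[["f_sc"]] - target_f_sc) > 0.02)
    warning(sprintf(
      "island-model calibration off target (F_CT %.3f vs %.3f, F_SC %.3f vs %.3f)",
      achieved[["f_ct"]], target_f_ct, achieved[["f_sc"]], target_f_sc))
  structure(list(table = sim$table, m_within = m_w, m_among = m_a,
                 achieved = achieved,
                 targets = c(f_ct = target_f_ct, f_sc = target_f_sc),
                 groups = groups, demes_per_group = demes_per_group,
                 sample_config = sample_config, seed = seed),
            class = "null_fdist")
}

#' Re-simulate loci from an already calibrated island-model null
#'
#' Draws a fresh set of independent loci from the hierarchical island
#' model of a [simulate_null_fdist()] result, without re-running the
#' migration-rate calibration.
#'
#' @param null a `null_fdist`.
#' @param n_loci number of loci to simulate.
#' @param seed integer seed.
#' @return A locus table like `null$table`.
#' @export
resimulate_null_fdist <- function(null, n_loci, seed = 1L) {
  stopifnot(inherits(null, "null_fdist"))
  island_locus_table(n_loci, null$groups, null$demes_per_group,
                     null$m_within, null$m_among, null$sample_config,
                     seed)$table
}

#' Heterozygosity-conditioned null envelope of F_CT
#'
#' Splits the simulated loci into equal-count heterozygosity bins and
#' stores the per-bin empirical `F_CT` quantiles at significance `alpha`
#' (two-sided: `alpha/2` in each tail).
#'
#' @param sim simulated locus table (a `null_fdist` or its `$table`).
#' @param n_bins number of equal-count heterozygosity bins.
#' @param alpha two-sided significance level.
#' @return A list of class `null_envelope`.
#' @export
null_envelope <- function(sim, n_bins = 20L, alpha = 0.01) {
  tab <- if (inherits(sim, "null_fdist")) sim$table else sim
  tab <- tab[is.finite(tab$f_ct) & is.finite(tab$heterozygosity), ]
  breaks <- unique(quantile(tab$heterozygosity,
                            probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE))
  bin <- findInterval(tab$heterozygosity, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  fct_by_bin <- split(tab$f_ct, bin)
  lower <- vapply(fct_by_bin, quantile, numeric(1), probs = alpha / 2,
                  names = FALSE)
  upper <- vapply(fct_by_bin, quantile, numeric(1), probs = 1 - alpha / 2,
                  names = FALSE)
  structure(list(breaks = breaks, fct_by_bin = fct_by_bin,
                 lower = lower, upper = upper, alpha = alpha,
                 het_range = range(tab$heterozygosity)),
            class = "null_envelope")
}

#' Classify loci against the coalescent null envelope
#'
#' Each observed locus is placed in the heterozygosity bin of the null
#' envelope and compared with the per-bin empirical `F_CT` distribution:
#' loci above the `1 - alpha/2` quantile are classified `divergent`
#' (candidate divergent selection), below the `alpha/2` quantile
#' `balancing`, otherwise `neutral`.  The reported `p` is the empirical
#' tail probability of the closer tail, `(count + 1) / (n_bin + 1)`.
#' Monomorphic loci stay unclassified (`NA`); loci whose heterozygosity
#' falls outside the simulated range use the nearest bin and are flagged.
#'
#' @param observed observed locus table as from [locus_fstats_all()].
#' @param null a [null_envelope()] (or a `null_fdist`, binned with the
#'   defaults at the given `alpha`).
#' @param alpha two-sided significance level; must match the envelope.
#' @return The observed table with columns `p`, `class` and
#'   `out_of_range` appended.
#' @export
classify_outliers <- function(observed, null, alpha = 0.01) {
  stopifnot(alpha > 0, alpha <= 1)
  if (inherits(null, "null_fdist")) null <- null_envelope(null, alpha = alpha)
  if (abs(null$alpha - alpha) > 1e-12)
    stop("envelope was built at a different significance level")
  out <- observed
  nb <- length(null$fct_by_bin)
  bin <- findInterval(out$heterozygosity, null$breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
  bin <- pmin(pmax(bin, 1L), nb)
  out$out_of_range <- out$heterozygosity < null$het_range[1] |
    out$heterozygosity > null$het_range[2]
  out$p <- NA_real_
  out$class <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (!is.finite(out$f_ct[i])) next
    sims <- null$fct_by_bin[[bin[i]]]
    n <- length(sims)
    p_up <- (sum(sims >= out$f_ct[i]) + 1) / (n + 1)
    p_lo <- (sum(sims <= out$f_ct[i]) + 1) / (n + 1)
    out$p[i] <- min(p_up, p_lo)
    out$class[i] <- if (out$f_ct[i] > null$upper[bin[i]]) "divergent"
      else if (out$f_ct[i] < null$lower[bin[i]]) "balancing"
      else "neutral"
  }
  out
}
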