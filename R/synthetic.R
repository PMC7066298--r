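# Seeded generators for every input the pipeline consumes: genotype
# datasets under the seven divergence scenarios, hierarchically
# structured SNP panels, and climate/occurrence sets with controlled
# niche overlap.  Each generator records a truth record sufficient to
# regenerate the dataset exactly.

truth_record <- function(kind, params, seed, sample_config) {
  structure(list(kind = kind, params = params, seed = seed,
                 sample_config = sample_config),
            class = "truth_record")
}

#' Write / read a truth record as JSON
#' @param truth a truth record as returned by the generators.
#' @param file path of the JSON file.
#' @return `file` invisibly for the writer; a `truth_record` for the
#'   reader.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  structure(jsonlite::read_json(file, simplifyVector = TRUE),
            class = "truth_record")
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  cbind(ref = ref, alt = unname(alt))
}

#' Simulate a two-species RAD dataset under a divergence scenario
#'
#' One genealogy per locus is drawn from the compiled scenario (for the
#' `2M` families the locus class is Bernoulli(`P`)); exactly one
#' segregating site per locus is emitted, its branch chosen proportional
#' to length.  Diploid genotypes are formed by pairing consecutive
#' simulated chromosomes.  The outgroup individual carries the
#' homozygous ancestral allele, flipped to the derived allele with
#' probability `misorientation_rate`.  The derived allele is written as
#' REF or ALT with equal probability, so polarization is non-trivial.
#'
#' @param p a [param_vector()].
#' @param n_loci number of RAD loci (= SNPs).
#' @param diploids_per_pop length-2 integer: diploid individuals sampled
#'   per population.
#' @param theta_per_locus scaled per-locus mutation rate, recorded in the
#'   truth record.  With exactly one site emitted per locus it does not
#'   change the shape of the simulated spectrum.
#' @param misorientation_rate probability that the outgroup shows the
#'   derived allele (ancestral-state misorientation).
#' @param seed integer seed; the dataset is deterministic given the seed.
#' @return A list with the [genotype_matrix()] `genotypes` (outgroup
#'   column `"outgroup"`), the `truth` record, and the true per-site
#'   `derived`-allele dosage matrix for validation.
#' @export
simulate_divergence_dataset <- function(p, n_loci, diploids_per_pop = c(16L, 8L),
                                        theta_per_locus = 1,
                                        misorientation_rate = 0,
                                        seed = 1L) {
  stopifnot(n_loci >= 1, length(diploids_per_pop) == 2)
  model_id <- attr(p, "model_id")
  n1 <- 2L * diploids_per_pop[1]; n2 <- 2L * diploids_per_pop[2]
  with_seed(seed, {
    if (is_2m_model(model_id)) {
      free <- runif(n_loci) < p[["P"]]
      ep_free <- epochs_for_engine(compile_scenario(p, "free"))
      ep_restr <- epochs_for_engine(compile_scenario(p, "restricted"))
      hap <- matrix(0L, n_loci, n1 + n2)
      if (any(free))
        hap[free, ] <- .coal_sim_snps_cpp(
          c(rep(0L, n1), rep(1L, n2)), ep_free, sum(free))
      if (any(!free))
        hap[!free, ] <- .coal_sim_snps_cpp(
          c(rep(0L, n1), rep(1L, n2)), ep_restr, sum(!free))
    } else {
      hap <- .coal_sim_snps_cpp(c(rep(0L, n1), rep(1L, n2)),
                                epochs_for_engine(compile_scenario(p)),
                                n_loci)
    }
    odd <- seq(1L, n1 + n2, by = 2L)
    derived_dos <- hap[, odd, drop = FALSE] + hap[, odd + 1L, drop = FALSE]
    derived_is_alt <- runif(n_loci) < 0.5
    dos <- derived_dos
    dos[!derived_is_alt, ] <- 2L - dos[!derived_is_alt, , drop = FALSE]
    og_derived <- runif(n_loci) < misorientation_rate
    og <- ifelse(og_derived == derived_is_alt, 2L, 0L)
    al <- random_alleles(n_loci)
    sites <- data.frame(
      locus = sprintf("locus%06d", seq_len(n_loci)),
      id = sprintf("locus%06d_snp1", seq_len(n_loci)),
      pos = sample.int(10000L, n_loci, replace = TRUE),
      ref = al[, "ref"], alt = al[, "alt"],
      ancestral = "unknown", stringsAsFactors = FALSE)
    inds <- c(sprintf("p1_%03d", seq_len(diploids_per_pop[1])),
              sprintf("p2_%03d", seq_len(diploids_per_pop[2])),
              "outgroup")
    geno <- cbind(dos, og)
    colnames(geno) <- inds
    pop_labels <- setNames(rep(c("pop1", "pop2"), diploids_per_pop),
                           inds[-length(inds)])
    g <- genotype_matrix(geno, sites, pop_labels,
                         c(pop1 = "sp1", pop2 = "sp2"))
    truth <- truth_record("divergence",
                          c(as.list(setNames(as.numeric(p), names(p))),
                            list(model_id = model_id,
                                 theta_per_locus = theta_per_locus,
                                 misorientation_rate = misorientation_rate,
                                 n_loci = n_loci)),
                          seed,
                          list(diploids_per_pop = diploids_per_pop))
    list(genotypes = g, truth = truth, derived = derived_dos)
  })
}

#' Simulate a hierarchically structured SNP panel
#'
#' Independent one-SNP loci under the equilibrium hierarchical island
#' coalescent: `groups` groups of `demes_per_group` demes, within-group
#' total scaled migration `m_within` and among-group `m_among`.
#'
#' @param groups,demes_per_group,m_within,m_among island-model
#'   configuration, see [island_scenario()].
#' @param n_loci number of loci.
#' @param diploids_per_deme diploids sampled from each of
#'   `demes_sampled` demes per group.
#' @param demes_sampled demes sampled per group.
#' @param seed integer seed.
#' @return A list with `genotypes` (a [genotype_matrix()] whose
#'   populations are demes `G<g>D<d>` grouped by `G<g>`) and `truth`.
#' @export
simulate_hierarchical_island_dataset <- function(groups = 2L,
                                                 demes_per_group = 10L,
                                                 m_within = 10, m_among = 1,
                                                 n_loci = 1000L,
                                                 diploids_per_deme = 10L,
                                                 demes_sampled = 3L,
                                                 seed = 1L) {
  cfg <- island_sample_config(groups, demes_sampled, diploids_per_deme)
  sim <- island_locus_table(n_loci, groups, demes_per_group, m_within,
                            m_among, cfg, seed)
  n_ind <- length(sim$pop_of_ind)
  inds <- sprintf("%s_i%02d", sim$pop_of_ind,
                  stats::ave(seq_len(n_ind), sim$pop_of_ind, FUN = seq_along))
  geno <- sim$dosage
  colnames(geno) <- inds
  al <- with_seed(derive_seed(seed, 17L), random_alleles(n_loci))
  sites <- data.frame(
    locus = sprintf("locus%06d", seq_len(n_loci)),
    id = sprintf("locus%06d_snp1", seq_len(n_loci)),
    pos = seq_len(n_loci), ref = al[, "ref"], alt = al[, "alt"],
    ancestral = "unknown", stringsAsFactors = FALSE)
  pops <- unique(sim$pop_of_ind)
  g <- genotype_matrix(geno, sites,
                       setNames(sim$pop_of_ind, inds),
                       setNames(sub("D.*", "", pops), pops))
  truth <- truth_record("hierarchical_island",
                        list(groups = groups,
                             demes_per_group = demes_per_group,
                             m_within = m_within, m_among = m_among,
                             n_loci = n_loci),
                        seed,
                        list(diploids_per_deme = diploids_per_deme,
                             demes_sampled = demes_sampled))
  list(genotypes = g, truth = truth)
}

#' Simulate a two-species climate/occurrence dataset
#'
#' Background cells are drawn from a broad mixture spanning a latent
#' 2-D climate space and mapped to `n_variables` correlated climate
#' variables through a fixed loading matrix plus noise.  Each species'
#' occurrences sample background cells with weights from a Gaussian
#' niche; the niche centroids are `centroid_separation` apart along the
#' first latent axis (0 = identical niches).
#'
#' @param n_background number of background cells.
#' @param n_occ1,n_occ2 occurrences per species.
#' @param n_variables number of climate variables (>= 2).
#' @param centroid_separation distance between the two niche centroids
#'   in latent units (niche sd = 1).
#' @param seed integer seed.
#' @return A list with the [climate_table()] `climate` and `truth`.
#' @export
simulate_niche_dataset <- function(n_background = 2000L, n_occ1 = 100L,
                                   n_occ2 = 100L, n_variables = 7L,
                                   centroid_separation = 0, seed = 1L) {
  stopifnot(n_background >= 3, n_occ1 >= 1, n_occ2 >= 1, n_variables >= 2)
  with_seed(seed, {
    # latent climate space: broad two-component mixture
    comp <- sample(0:1, n_background, replace = TRUE, prob = c(0.6, 0.4))
    latent <- cbind(rnorm(n_background, ifelse(comp == 1, 1.5, -1), 2),
                    rnorm(n_background, ifelse(comp == 1, -0.5, 0.5), 2))
    W <- matrix(rnorm(2 * n_variables), 2, n_variables)
    bg <- latent %*% W + matrix(rnorm(n_background * n_variables, sd = 0.3),
                                n_background, n_variables)
    colnames(bg) <- sprintf("bio%02d", seq_len(n_variables))
    centroids <- list(sp1 = c(-centroid_separation / 2, 0),
                      sp2 = c(centroid_separation / 2, 0))
    draw_occ <- function(n, centre) {
      w <- exp(-0.5 * ((latent[, 1] - centre[1])^2 +
                         (latent[, 2] - centre[2])^2))
      sample(n_background, n, replace = TRUE, prob = w)
    }
    ct <- climate_table(as.data.frame(bg),
                        list(sp1 = draw_occ(n_occ1, centroids$sp1),
                             sp2 = draw_occ(n_occ2, centroids$sp2)))
    truth <- truth_record("niche",
                          list(centroid_separation = centroid_separation,
                               centroids = centroids, niche_sd = 1,
                               n_variables = n_variables),
                          seed,
                          list(n_background = n_background,
                               n_occ = c(n_occ1, n_occ2)))
    list(climate = ct, truth = truth)
  })
}

#' Write a climate table as plain-text CSV files
#'
#' The background goes to `<prefix>_background.csv` (cells x variables)
#' and the occurrences of each species to `<prefix>_<species>.csv` with
#' a single `cell` column of background row indices.
#'
#' @param t a [climate_table()].
#' @param prefix output path prefix.
#' @return The written file paths, invisibly.
#' @export
write_climate_csv <- function(t, prefix) {
  paths <- paste0(prefix, "_background.csv")
  utils::write.csv(t$background, paths, row.names = FALSE)
  for (nm in names(t$occurrences)) {
    f <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(data.frame(cell = t$occurrences[[nm]]), f,
                     row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Read a climate table written by [write_climate_csv()]
#'
#' @param background_file background CSV (cells x variables).
#' @param occurrence_files named character vector of per-species
#'   occurrence CSVs with a `cell` column.
#' @return A [climate_table()].
#' @export
read_climate_csv <- function(background_file, occurrence_files) {
  bg <- utils::read.csv(background_file)
  occ <- lapply(occurrence_files, function(f) utils::read.csv(f)$cell)
  names(occ) <- names(occurrence_files)
  climate_table(bg, occ)
}
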