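# Climatic niche quantification: PCA ordination of the background
# environment, availability-corrected kernel densities of occurrences in
# the first two principal axes, Schoener's D, and the niche equivalency
# and similarity permutation tests.

#' Climate background and species occurrences
#'
#' @param background data.frame of climate variables, one row per
#'   background cell (at least 2 variables, no missing values).
#' @param occurrences named list of integer vectors, one per species,
#'   each indexing rows of `background` (the cell holding each
#'   occurrence).
#' @return An object of class `climate_table`.
#' @export
climate_table <- function(background, occurrences) {
  background <- as.data.frame(background)
  if (ncol(background) < 2) stop("need at least 2 climate variables")
  if (anyNA(background)) stop("background cells must have no missing values")
  stopifnot(is.list(occurrences), length(occurrences) >= 1)
  for (occ in occurrences) {
    if (length(occ) < 1 || any(occ < 1 | occ > nrow(background)))
      stop("every occurrence must map to a background cell")
  }
  structure(list(background = background, occurrences = occurrences),
            class = "climate_table")
}

#' @export
print.climate_table <- function(x, ...) {
  cat("climate_table:", nrow(x$background), "background cells,",
      ncol(x$background), "variables\n")
  for (nm in names(x$occurrences))
    cat("  ", nm, ": ", length(x$occurrences[[nm]]), " occurrences\n",
        sep = "")
  invisible(x)
}

#' PCA ordination of climate space on the background environment
#'
#' Variables are centered and standardized on the background cells and
#' the principal axes computed from the background covariance; species
#' occurrences are projected onto the first two axes.
#'
#' @param t a [climate_table()].
#' @return A list with `background` (n x 2 score matrix), `species`
#'   (list of score matrices), `sdev` and `rotation`.
#' @export
pca_env_scores <- function(t) {
  stopifnot(inherits(t, "climate_table"))
  if (nrow(t$background) < 3) stop("need at least 3 background cells")
  sds <- vapply(t$background, sd, numeric(1))
  if (any(sds == 0)) stop("constant climate variable: ",
                          paste(names(sds)[sds == 0], collapse = ", "))
  pc <- prcomp(t$background, center = TRUE, scale. = TRUE)
  bg <- pc$x[, 1:2, drop = FALSE]
  sp <- lapply(t$occurrences, function(idx) bg[idx, , drop = FALSE])
  list(background = bg, species = sp, sdev = pc$sdev,
       rotation = pc$rotation)
}

# Normal-reference-rule bandwidth (as an sd) per axis, with fallback when
# the points have no spread.
nrd_sd <- function(x, fallback) {
  if (length(x) < 2) return(fallback)
  h <- MASS::bandwidth.nrd(x) / 4
  if (!is.finite(h) || h <= 0) fallback else h
}

# Gaussian product-kernel density on a fixed grid.
kern2d <- function(pts, gx, gy, hx, hy) {
  Kx <- outer(gx, pts[, 1], function(g, p) stats::dnorm(g, p, hx))
  Ky <- outer(gy, pts[, 2], function(g, p) stats::dnorm(g, p, hy))
  (Kx %*% t(Ky)) / nrow(pts)
}

#' Availability-corrected occurrence density in PCA climate space
#'
#' Gaussian kernel density of the occurrences and of the background on a
#' common `R x R` grid spanning the background score range.  The
#' occurrence density is divided by the background availability where
#' available, zeroed where the background density vanishes, and
#' renormalized to sum to 1, so `z` is the occupancy of environments
#' relative to their availability.
#'
#' @param scores occurrence score matrix (n x 2).
#' @param background_scores background score matrix.
#' @param R grid resolution per axis.
#' @param bandwidth optional numeric length-2 kernel sd per axis;
#'   defaults to the normal-reference rule on the occurrence scores.
#' @return A list of class `env_density` with the normalized occupancy
#'   `z`, the normalized background availability `bg`, and the grid
#'   vectors `x`, `y`.
#' @export
density_grid <- function(scores, background_scores, R = 100L,
                         bandwidth = NULL) {
  scores <- rbind(scores)
  if (nrow(scores) < 1) stop("need at least one occurrence")
  rx <- range(background_scores[, 1]); ry <- range(background_scores[, 2])
  pad <- 0.05
  rx <- rx + c(-1, 1) * pad * diff(rx); ry <- ry + c(-1, 1) * pad * diff(ry)
  gx <- seq(rx[1], rx[2], length.out = R)
  gy <- seq(ry[1], ry[2], length.out = R)
  hbx <- nrd_sd(background_scores[, 1], diff(rx) / 25)
  hby <- nrd_sd(background_scores[, 2], diff(ry) / 25)
  if (is.null(bandwidth))
    bandwidth <- c(nrd_sd(scores[, 1], hbx), nrd_sd(scores[, 2], hby))
  occ <- kern2d(scores, gx, gy, bandwidth[1], bandwidth[2])
  bg <- kern2d(rbind(background_scores), gx, gy, hbx, hby)
  bg_floor <- max(bg) * 1e-8
  z <- ifelse(bg > bg_floor, occ / pmax(bg, bg_floor), 0)
  z <- z / sum(z)
  structure(list(z = z, bg = bg / sum(bg), x = gx, y = gy),
            class = "env_density")
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the gridded, normalized occupancy
#' densities: 0 for disjoint niches, 1 for identical niches.
#'
#' @param z1,z2 [density_grid()] results on the same grid.
#' @return Overlap in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2) {
  if (!identical(dim(z1$z), dim(z2$z)) || !isTRUE(all.equal(z1$x, z2$x)) ||
      !isTRUE(all.equal(z1$y, z2$y)))
    stop("densities must live on the same grid")
  max(0, min(1, 1 - 0.5 * sum(abs(z1$z - z2$z))))
}

# Observed D of the first two species of a climate table, with the PCA
# and background density computed once.
observed_overlap <- function(t, R = 100L) {
  sc <- pca_env_scores(t)
  sp <- names(t$occurrences)[1:2]
  z1 <- density_grid(sc$species[[sp[1]]], sc$background, R)
  z2 <- density_grid(sc$species[[sp[2]]], sc$background, R)
  list(scores = sc, sp = sp, z1 = z1, z2 = z2, d = schoener_d(z1, z2))
}

#' Niche equivalency permutation test
#'
#' Pools the occurrences of the two species and randomly reassigns them
#' to the species at their original sample sizes; Schoener's D is
#' recomputed for each permutation.  `p = (count of null D <= observed
#' + 1) / (B + 1)`: a low observed overlap relative to the pooled null
#' rejects niche equivalency (`p <= 0.05`).
#'
#' @param t a [climate_table()] with two species.
#' @param n_permutations number of permutations `B`.
#' @param seed integer seed.
#' @param R density grid resolution.
#' @return A list of class `niche_test` with `observed_d`, `null_d`
#'   (length `B`) and `p`.
#' @export
equivalency_test <- function(t, n_permutations = 100L, seed = 1L, R = 100L) {
  obs <- observed_overlap(t, R)
  n1 <- length(t$occurrences[[obs$sp[1]]])
  pool <- c(t$occurrences[[obs$sp[1]]], t$occurrences[[obs$sp[2]]])
  bg <- obs$scores$background
  null_d <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    idx <- sample(length(pool))
    o1 <- pool[idx[seq_len(n1)]]
    o2 <- pool[idx[-seq_len(n1)]]
    schoener_d(density_grid(bg[o1, , drop = FALSE], bg, R),
               density_grid(bg[o2, , drop = FALSE], bg, R))
  }, numeric(1)))
  p <- (sum(null_d <= obs$d) + 1) / (n_permutations + 1)
  structure(list(test = "equivalency", observed_d = obs$d, null_d = null_d,
                 p = p), class = "niche_test")
}

#' Niche similarity permutation test
#'
#' For each permutation, one species' occurrence cloud is translated so
#' that its centroid lands on a random point of the background
#' environment (its availability), D is recomputed against the other
#' species, and the two directions are averaged.
#' `p = (count of null D >= observed + 1) / (B + 1)`: niches more
#' similar than random expectation give `p <= 0.05`.
#'
#' @inheritParams equivalency_test
#' @return A list of class `niche_test` with `observed_d`, `null_d` and
#'   `p`.
#' @export
similarity_test <- function(t, n_permutations = 100L, seed = 1L, R = 100L) {
  obs <- observed_overlap(t, R)
  bg <- obs$scores$background
  s1 <- obs$scores$species[[obs$sp[1]]]
  s2 <- obs$scores$species[[obs$sp[2]]]
  shift_to <- function(s, target) {
    sweep(s, 2, colMeans(s) - target, `-`)
  }
  null_d <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    c1 <- bg[sample(nrow(bg), 1L), ]
    c2 <- bg[sample(nrow(bg), 1L), ]
    d1 <- schoener_d(density_grid(shift_to(s1, c1), bg, R), obs$z2)
    d2 <- schoener_d(obs$z1, density_grid(shift_to(s2, c2), bg, R))
    (d1 + d2) / 2
  }, numeric(1)))
  p <- (sum(null_d >= obs$d) + 1) / (n_permutations + 1)
  structure(list(test = "similarity", observed_d = obs$d, null_d = null_d,
                 p = p), class = "niche_test")
}

#' @export
print.niche_test <- function(x, ...) {
  cat(sprintf("niche %s test: observed D = %.3f, p = %.4g (B = %d)\n",
              x$test, x$observed_d, x$p, length(x$null_d)))
  invisible(x)
}
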