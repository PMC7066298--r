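#' Two-dimensional joint allele frequency spectrum
#'
#' An unfolded joint allele frequency spectrum (JAFS) over derived-allele
#' counts `0..n1` in population 1 and `0..n2` in population 2, together
#' with a boolean mask.  The monomorphic corners `(0, 0)` and `(n1, n2)`
#' carry no information about polymorphism and are masked by default.
#'
#' @param values numeric `(n1+1) x (n2+1)` matrix of nonnegative entries.
#' @param mask logical matrix of the same shape (`TRUE` = masked); by
#'   default only the two corners are masked.
#' @param kind `"observed"` or `"expected"`.
#' @return An object of class `jafs`.
#' @export
jafs <- function(values, mask = NULL, kind = c("observed", "expected")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("JAFS entries must be finite and >= 0")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  mask <- as.matrix(mask)
  stopifnot(identical(dim(mask), dim(values)))
  mask[1L, 1L] <- TRUE
  mask[nrow(mask), ncol(mask)] <- TRUE
  structure(list(values = values, mask = mask,
                 n1 = nrow(values) - 1L, n2 = ncol(values) - 1L,
                 kind = kind),
            class = "jafs")
}

#' @export
print.jafs <- function(x, ...) {
  cat(sprintf("jafs (%s): %d x %d chromosomes, unmasked mass %.4g\n",
              x$kind, x$n1, x$n2, jafs_mass(x)))
  invisible(x)
}

#' Total unmasked mass of a spectrum
#' @param s a [jafs()] object.
#' @return Sum of the unmasked entries.
#' @export
jafs_mass <- function(s) sum(s$values[!s$mask])

#' Polarize sites with an outgroup individual and drop unpolarizable sites
#'
#' Sets the per-site ancestral state to the allele carried homozygously by
#' the outgroup.  Sites where the outgroup is missing, heterozygous, or
#' homozygous for an allele absent from the ingroup are dropped, following
#' the conservative rule that an ambiguous outgroup cannot orient the
#' site.  The outgroup column is removed from the returned matrix.
#'
#' @param g a [genotype_matrix()] containing the outgroup as a column.
#' @param outgroup_individual column name of the outgroup individual.
#' @return A polarized [genotype_matrix()] without the outgroup column.
#' @export
polarize_and_filter <- function(g, outgroup_individual) {
  if (!outgroup_individual %in% colnames(g$geno))
    stop("unknown outgroup individual: ", outgroup_individual)
  if (outgroup_individual %in% names(g$pop))
    stop("outgroup individual must not carry a population label")
  og <- g$geno[, outgroup_individual]
  keep <- !is.na(og) & og %in% c(0L, 2L)
  g <- subset_sites(g, keep)
  og <- og[keep]
  g$sites$ancestral <- ifelse(og == 0L, "ref", "alt")
  g$geno <- g$geno[, colnames(g$geno) != outgroup_individual, drop = FALSE]
  g
}

#' Keep one randomly chosen SNP per locus
#'
#' RAD loci contribute several linked SNPs; model fitting assumes unlinked
#' sites, so exactly one SNP per locus is retained, chosen uniformly at
#' random under the given seed.
#'
#' @param g a [genotype_matrix()].
#' @param seed integer seed; the choice is deterministic given the seed.
#' @return A [genotype_matrix()] with one site per locus.
#' @export
thin_one_snp_per_locus <- function(g, seed) {
  idx <- split(seq_len(n_sites(g)), factor(g$sites$locus,
                                           levels = unique(g$sites$locus)))
  keep <- with_seed(seed, vapply(idx, function(i) {
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
  }, integer(1)))
  subset_sites(g, sort(unname(keep)))
}

#' Build the unfolded joint allele frequency spectrum
#'
#' Tallies derived-allele counts of two populations into a
#' `(n1+1) x (n2+1)` spectrum.  Missing genotypes are handled per site by
#' hypergeometric projection from the called chromosome count down to the
#' target sizes `n1`/`n2`; sites with fewer called chromosomes than the
#' target in either population are dropped.  Monomorphic corners are
#' masked.
#'
#' @param g a polarized [genotype_matrix()].
#' @param pop1,pop2 population ids defining the two axes.
#' @param n1,n2 target chromosome sample sizes (at most twice the number
#'   of sampled individuals in each population).
#' @return A [jafs()] of kind `"observed"`.
#' @export
build_jafs <- function(g, pop1, pop2, n1, n2) {
  stopifnot(pop1 %in% g$pop, pop2 %in% g$pop)
  i1 <- names(g$pop)[g$pop == pop1]
  i2 <- names(g$pop)[g$pop == pop2]
  if (n1 > 2L * length(i1) || n2 > 2L * length(i2))
    stop("projection size exceeds sampled chromosomes")
  d <- derived_dosage(g)
  d1 <- d[, i1, drop = FALSE]; d2 <- d[, i2, drop = FALSE]
  c1 <- 2L * rowSums(!is.na(d1)); c2 <- 2L * rowSums(!is.na(d2))
  k1 <- rowSums(d1, na.rm = TRUE); k2 <- rowSums(d2, na.rm = TRUE)
  vals <- matrix(0, n1 + 1L, n2 + 1L)
  ok <- which(c1 >= n1 & c2 >= n2)
  for (s in ok) {
    p1 <- dhyper(0:n1, k1[s], c1[s] - k1[s], n1)
    p2 <- dhyper(0:n2, k2[s], c2[s] - k2[s], n2)
    vals <- vals + tcrossprod(p1, p2)
  }
  jafs(vals, kind = "observed")
}

#' Project a spectrum down to smaller sample sizes
#'
#' Redistributes every entry by the product of hypergeometric pmfs for
#' drawing `m1` of `n1` and `m2` of `n2` chromosomes.  Projection is
#' linear and conserves total (pre-mask) mass; the corners of the
#' projected spectrum are re-masked.
#'
#' @param s a [jafs()].
#' @param m1,m2 target sizes, `m1 <= n1`, `m2 <= n2`.
#' @return A [jafs()] of size `(m1+1) x (m2+1)`.
#' @export
project_jafs <- function(s, m1, m2) {
  if (m1 > s$n1 || m2 > s$n2)
    stop("projection target exceeds current spectrum size")
  v <- s$values
  v[s$mask] <- 0
  P1 <- outer(0:m1, 0:s$n1,
              function(a, i) dhyper(a, i, s$n1 - i, m1))
  P2 <- outer(0:m2, 0:s$n2,
              function(b, j) dhyper(b, j, s$n2 - j, m2))
  jafs(P1 %*% v %*% t(P2), kind = s$kind)
}

#' Write a spectrum in the flat-text frequency-spectrum format
#'
#' Line 1: `"<n1+1> <n2+1> unfolded"`; line 2: row-major values; line 3:
#' row-major mask (1 = masked).  Values are written with full precision so
#' the reader round-trips bit-faithfully.
#'
#' @param s a [jafs()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sfs <- function(s, file) {
  lines <- c(
    paste(s$n1 + 1L, s$n2 + 1L, "unfolded"),
    paste(sprintf("%.17g", as.vector(t(s$values))), collapse = " "),
    paste(as.integer(as.vector(t(s$mask))), collapse = " "))
  writeLines(lines, file)
  invisible(file)
}

#' Read a spectrum from the flat-text frequency-spectrum format
#'
#' @param file path written by [write_sfs()] (or any file in the same
#'   three-line format).
#' @param kind `"observed"` or `"expected"`.
#' @return A [jafs()].
#' @export
read_sfs <- function(file, kind = "observed") {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  d1 <- as.integer(hdr[1L]); d2 <- as.integer(hdr[2L])
  vals <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  msk <- as.integer(strsplit(trimws(lines[3L]), "\\s+")[[1L]])
  if (length(vals) != d1 * d2 || length(msk) != d1 * d2)
    stop("malformed frequency-spectrum file")
  jafs(matrix(vals, d1, d2, byrow = TRUE),
       mask = matrix(msk == 1L, d1, d2, byrow = TRUE), kind = kind)
}
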