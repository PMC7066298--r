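#' Per-locus, per-individual diploid genotype container
#'
#' Holds biallelic SNP genotypes as alt-allele dosage together with the
#' population label of every individual, the species/group label of every
#' population, and the per-site ancestral state used to polarize spectra.
#'
#' Encoding: genotypes are integers in `{0, 1, 2}` (copies of the alt
#' allele), `NA` for missing.  The value `3` is reserved for an individual
#' homozygous for an allele seen in neither REF nor ALT of the ingroup
#' (it can only arise in an outgroup column read from a multi-allelic
#' VCF record) and is treated as unpolarizable.
#'
#' @param geno integer matrix, sites x individuals, values in
#'   `{0, 1, 2, 3, NA}`; rownames are site ids, colnames individual ids.
#' @param sites data.frame with columns `locus`, `id`, `pos`, `ref`, `alt`
#'   and `ancestral` (one of `"ref"`, `"alt"`, `"unknown"`), one row per
#'   genotype row.
#' @param pop_labels named character vector: population id per individual.
#'   Individuals absent from it (e.g. an outgroup sample) carry no
#'   population.
#' @param group_labels named character vector: group (species) id per
#'   population.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, pop_labels, group_labels) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == nrow(sites))
  need <- c("locus", "id", "pos", "ref", "alt", "ancestral")
  if (!all(need %in% names(sites)))
    stop("`sites` must have columns: ", paste(need, collapse = ", "))
  bad <- !(geno %in% c(0L, 1L, 2L, 3L) | is.na(geno))
  if (any(bad)) stop("genotype values must be in {0, 1, 2, 3, NA}")
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  rownames(geno) <- sites$id
  pop_labels <- pop_labels[!is.na(pop_labels)]
  unknown_ind <- setdiff(names(pop_labels), colnames(geno))
  if (length(unknown_ind))
    stop("pop_labels name individuals absent from the genotype matrix: ",
         paste(unknown_ind, collapse = ", "))
  pops <- unique(unname(pop_labels))
  if (!all(pops %in% names(group_labels)))
    stop("every population needs a group label")
  ingroup3 <- geno[, intersect(colnames(geno), names(pop_labels)), drop = FALSE] == 3L
  if (any(ingroup3, na.rm = TRUE))
    stop("code 3 (non-ingroup allele) is only valid for outgroup individuals")
  structure(
    list(geno = geno,
         sites = as.data.frame(sites, stringsAsFactors = FALSE),
         pop = pop_labels,
         groups = group_labels[pops]),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "sites x", ncol(x$geno),
      "individuals\n")
  cat("  loci:", length(unique(x$sites$locus)),
      " populations:", paste(unique(unname(x$pop)), collapse = ", "), "\n")
  cat("  groups:", paste(unique(unname(x$groups)), collapse = ", "), "\n")
  pol <- table(factor(x$sites$ancestral, c("ref", "alt", "unknown")))
  cat("  ancestral states: ref", pol[["ref"]], "/ alt", pol[["alt"]],
      "/ unknown", pol[["unknown"]], "\n")
  invisible(x)
}

n_sites <- function(g) nrow(g$geno)

# Derived-allele dosage per site x individual (requires polarized sites).
derived_dosage <- function(g) {
  anc <- g$sites$ancestral
  if (any(anc == "unknown"))
    stop("unpolarized site encountered; run polarize_and_filter() first")
  d <- g$geno
  flip <- anc == "alt"
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d
}

subset_sites <- function(g, keep) {
  g$sites <- g$sites[keep, , drop = FALSE]
  g$geno <- g$geno[keep, , drop = FALSE]
  rownames(g$sites) <- NULL
  g
}

#' Read genotypes from a VCF file
#'
#' Parses a diploid VCF 4.x file (GT field, unphased or phased) into a
#' [genotype_matrix()].  The CHROM column is taken as the RAD locus id, so
#' several records on one CHROM are SNPs of the same locus.  Records whose
#' ingroup samples show more than two alleles are dropped; an outgroup
#' sample homozygous for a third allele is encoded as `3` and removed
#' later by [polarize_and_filter()].
#'
#' @param file path to an (uncompressed or gzipped) VCF file.
#' @param pop_map data.frame with columns `individual` and `pop`;
#'   individuals not listed (e.g. the outgroup) carry no population.
#' @param group_map data.frame with columns `pop` and `group`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(file, pop_map, group_map) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt %in% c(".", "./.", ".|.")] <- NA
  inds <- colnames(gt)
  pop_labels <- setNames(as.character(pop_map$pop), pop_map$individual)
  pop_labels <- pop_labels[names(pop_labels) %in% inds]
  group_labels <- setNames(as.character(group_map$group), group_map$pop)
  ingroup <- intersect(inds, names(pop_labels))

  a1 <- sub("[/|].*", "", gt)
  a2 <- sub(".*[/|]", "", gt)
  suppressWarnings({
    a1 <- matrix(as.integer(a1), nrow(gt), ncol(gt), dimnames = dimnames(gt))
    a2 <- matrix(as.integer(a2), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  })
  # ingroup must be biallelic in {0,1}; drop records violating that
  ig1 <- a1[, ingroup, drop = FALSE]; ig2 <- a2[, ingroup, drop = FALSE]
  ok <- apply(ig1 <= 1L & ig2 <= 1L, 1L, all, na.rm = TRUE)
  dosage <- a1 + a2
  # outgroup (or any non-ingroup) columns: third alleles -> code 3
  third <- (a1 >= 2L) | (a2 >= 2L)
  dosage[third] <- 3L
  dosage[third & (a1 != a2)] <- 1L  # het involving a third allele: het
  alt1 <- sub(",.*", "", fix$ALT)
  sites <- data.frame(
    locus = fix$CHROM,
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = alt1,
    ancestral = "unknown",
    stringsAsFactors = FALSE)
  genotype_matrix(dosage[ok, , drop = FALSE], sites[ok, , drop = FALSE],
                  pop_labels, group_labels)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal diploid VCF 4.2 with GT-only genotype columns, suitable
#' for round-tripping through [read_genotypes()].
#'
#' @param g a [genotype_matrix()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_vcf_genotypes <- function(g, file) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divcoal",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g$geno)), collapse = "\t"))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gtxt <- matrix("./.", nrow(g$geno), ncol(g$geno))
  for (v in names(code)) gtxt[which(g$geno == as.integer(v))] <- code[[v]]
  body <- apply(cbind(g$sites$locus, g$sites$pos, g$sites$id, g$sites$ref,
                      g$sites$alt, ".", "PASS", ".", "GT", gtxt),
                1L, paste, collapse = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}
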