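Package: divcoal
Title: Demographic Inference of Two-Population Divergence from the Joint
    Allele Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the divergence history of two closely
    related species from reduced-representation SNP data.  Builds
    outgroup-polarized joint allele frequency spectra (JAFS) from VCF
    genotypes with hypergeometric projection, fits seven two-population
    divergence scenarios (strict isolation, isolation-with-migration,
    ancient migration, secondary contact, and their two-migration-class
    extensions) by composite Poisson likelihood with a Monte-Carlo
    structured-coalescent expectation engine and a multi-round perturbed
    Nelder-Mead protocol, and compares models by AIC.  Also provides a
    hierarchical-island-model coalescent null for FCT outlier scans with
    three-level AMOVA, niche-overlap quantification (Schoener's D with
    equivalency and similarity permutation tests) in PCA climate space,
    and seeded synthetic-data generators for all three analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
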