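Package: snpharmony
Title: Harmonization and Population-Genetic Analysis of Multi-Study SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for merging independently genotyped biallelic SNP datasets
    into a single range-wide panel. Resolves strand-designation conflicts at
    ambiguous (A/T and C/G) loci by allele-frequency calibration against
    geographic replicate samples, applies tiered locus quality control
    (missingness, Hardy-Weinberg testing with false-discovery-rate correction,
    replicate FST screening) with a full audit ledger, and computes the
    population-genetic statistics used in range-wide phylogeographic analysis:
    observed and expected heterozygosity, per-locus and multi-locus pairwise
    Weir-Cockerham FST, Mantel tests of isolation by distance on linearized
    FST, and Welch t comparisons of regional differentiation. A synthetic
    multi-dataset generator with a recorded truth ledger (Balding-Nichols
    divergence, stepping-stone isolation by distance, injected strand flips,
    one-sided ascertainment bias, dataset-specific missingness) provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
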