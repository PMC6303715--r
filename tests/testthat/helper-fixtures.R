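# Programmatic fixtures: panels built in code, no stored data files.

# Panel from an explicit dosage matrix, one location per block.
panel_from_dosages <- function(dosages, allele1 = "A", allele2 = "C",
                               locations = NULL, dataset = "D1",
                               locus_ids = NULL) {
  dosages <- as.matrix(dosages)
  L <- ncol(dosages)
  if (is.null(locus_ids)) locus_ids <- sprintf("L%03d", seq_len(L))
  if (is.null(locations)) locations <- rep("LOC1", nrow(dosages))
  loci <- data.frame(locus_id = locus_ids,
                     allele1 = rep_len(allele1, L),
                     allele2 = rep_len(allele2, L),
                     stringsAsFactors = FALSE)
  individuals <- data.frame(
    individual_id = paste0(dataset, "_", seq_len(nrow(dosages))),
    location_code = locations, stringsAsFactors = FALSE)
  genotype_panel(dosages, loci, individuals, dataset = dataset)
}

# Panel whose designated-allele frequencies hit the targets exactly:
# at each (location, locus) the allele count round(2n * f) is packed into
# homozygotes (plus one heterozygote for odd counts). Frequencies must be
# multiples of 1/(2n) to be hit exactly.
panel_from_freqs <- function(freqs, n, allele1 = "A", allele2 = "C",
                             dataset = "D1", id_prefix = dataset) {
  freqs <- as.matrix(freqs)
  L <- ncol(freqs)
  if (is.null(colnames(freqs))) colnames(freqs) <- sprintf("L%03d", seq_len(L))
  if (is.null(rownames(freqs)))
    rownames(freqs) <- sprintf("S%02d", seq_len(nrow(freqs)))
  blocks <- lapply(seq_len(nrow(freqs)), function(i) {
    cnt <- round(2 * n * freqs[i, ])
    vapply(cnt, function(cc) {
      g <- integer(n)
      g[seq_len(cc %/% 2)] <- 2L
      if (cc %% 2 == 1) g[cc %/% 2 + 1] <- 1L
      g
    }, integer(n))
  })
  dosages <- do.call(rbind, blocks)
  loci <- data.frame(locus_id = colnames(freqs),
                     allele1 = rep_len(allele1, L),
                     allele2 = rep_len(allele2, L), stringsAsFactors = FALSE)
  individuals <- data.frame(
    individual_id = paste0(id_prefix, "_", rep(rownames(freqs), each = n),
                           "_", rep(seq_len(n), nrow(freqs))),
    location_code = rep(rownames(freqs), each = n),
    stringsAsFactors = FALSE)
  genotype_panel(dosages, loci, individuals, dataset = dataset)
}

# Random panel for round-trip property tests. Every locus is guaranteed to
# show both alleles (individual 1 is a called heterozygote everywhere) so
# allele identities survive a Genepop round trip.
random_panel <- function(seed, n_loci = 8, n_locs = 3, n_per = 4,
                         missing_rate = 0.1, dataset = "D1") {
  set.seed(seed)
  n_ind <- n_locs * n_per
  pairs <- c("A/C", "A/G", "C/T", "G/T", "A/T", "C/G")
  pick <- sample(pairs, n_loci, replace = TRUE)
  a1 <- substr(pick, 1, 1); a2 <- substr(pick, 3, 3)
  swap <- runif(n_loci) < 0.5
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dosages <- matrix(sample(0:2, n_ind * n_loci, replace = TRUE), n_ind)
  dosages[runif(n_ind * n_loci) < missing_rate] <- NA_integer_
  dosages[1, ] <- 1L
  loci <- data.frame(locus_id = sprintf("rt%03d", seq_len(n_loci)),
                     allele1 = a1, allele2 = a2,
                     linkage_group = sample(c(NA, "LG1", "LG2"), n_loci,
                                            replace = TRUE),
                     stringsAsFactors = FALSE)
  individuals <- data.frame(
    individual_id = sprintf("%s_i%02d", dataset, seq_len(n_ind)),
    location_code = rep(sprintf("%s_s%d", dataset, seq_len(n_locs)),
                        each = n_per),
    stringsAsFactors = FALSE)
  genotype_panel(dosages, loci, individuals, dataset = dataset)
}

expect_panels_equal <- function(p, q) {
  expect_identical(unname(p$dosages), unname(q$dosages))
  expect_identical(p$loci$locus_id, q$loci$locus_id)
  expect_identical(p$loci$allele1, q$loci$allele1)
  expect_identical(p$loci$allele2, q$loci$allele2)
  expect_identical(p$individuals, q$individuals)
  expect_identical(p$samples$location_code, q$samples$location_code)
  expect_identical(p$samples$dataset, q$samples$dataset)
}

# Strand-decision sub-pipeline: intersect, calibrate on unambiguous shared
# loci, resolve all ambiguous shared loci. Returns the resolution table and
# calibration.
strand_pipeline <- function(sim, confidence = 0.95) {
  ix <- intersect_panels(sim$panels)
  ref_loci <- ix$panels[[1]]$loci
  amb <- is_ambiguous(ref_loci[match(ix$shared, ref_loci$locus_id), ])
  cal <- calibrate_strand_threshold(sim$pairs, ix$panels, ix$shared[!amb],
                                    confidence_requirement = confidence)
  res <- resolve_ambiguous_strands(sim$pairs, ix$panels, ix$shared[amb],
                                   cal$selected_threshold)
  list(calibration = cal, resolution = res, shared = ix$shared,
       ambiguous = ix$shared[amb])
}
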