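# Panel intersection, strand calibration/resolution, the tiered QC rules,
# and the full harmonization run against the generator's truth ledger.

# Two-panel fixture with one replicate locale whose frequencies are exact.
two_panel_fixture <- function(f_ref, f_alt, n = 50, allele1 = "A",
                              allele2 = "T", n_locales = 1) {
  f_ref <- as.matrix(f_ref); f_alt <- as.matrix(f_alt)
  stopifnot(nrow(f_ref) == n_locales, nrow(f_alt) == n_locales)
  rownames(f_ref) <- paste0("R", seq_len(n_locales))
  rownames(f_alt) <- paste0("A", seq_len(n_locales))
  colnames(f_alt) <- colnames(f_ref)
  p1 <- panel_from_freqs(f_ref, n, allele1, allele2, dataset = "REF")
  p2 <- panel_from_freqs(f_alt, n, allele1, allele2, dataset = "ALT")
  pairs <- replicate_pairs(paste0("loc", seq_len(n_locales)),
                           paste0("R", seq_len(n_locales)), "REF",
                           paste0("A", seq_len(n_locales)), "ALT")
  list(panels = list(REF = p1, ALT = p2), pairs = pairs)
}

test_that("intersect_panels takes the common locus set", {
  mk <- function(ids, ds) panel_from_dosages(
    matrix(1L, 2, length(ids)), "A", "C", dataset = ds, locus_ids = ids)
  out <- intersect_panels(list(mk(c("a", "b", "c"), "D1"),
                               mk(c("b", "c", "d"), "D2"),
                               mk(c("c", "b"), "D3")))
  expect_setequal(out$shared, c("b", "c"))
  expect_identical(out$private[[1]], "a")
  expect_identical(out$private[[2]], "d")
  expect_error(intersect_panels(list(mk("a", "D1"), mk("b", "D2"))),
               "zero shared")
})

test_that("reverse-complement allele pairs are reconciled, others conflict", {
  # panel 1 records G/T; panel 2 records the complement C/A:
  # C -> G (designation preserved after relabeling), A -> T
  p1 <- panel_from_dosages(matrix(c(2L, 1L, 0L), 3), "G", "T",
                           locus_ids = "l1")
  p2 <- panel_from_dosages(matrix(c(0L, 1L, 2L), 3), "C", "A",
                           dataset = "D2", locus_ids = "l1")
  out <- intersect_panels(list(p1, p2))
  expect_identical(out$shared, "l1")
  expect_identical(out$panels[[2]]$loci$allele1, "G")
  expect_identical(out$panels[[2]]$loci$allele2, "T")
  expect_identical(unname(out$panels[[2]]$dosages[, 1]), c(0L, 1L, 2L))
  # complement arriving in swapped order: designation swap recodes dosage
  p3 <- panel_from_dosages(matrix(c(0L, 1L, 2L), 3), "A", "C",
                           dataset = "D3", locus_ids = "l1")
  out2 <- intersect_panels(list(p1, p3))
  expect_identical(out2$panels[[2]]$loci$allele1, "G")
  expect_identical(unname(out2$panels[[2]]$dosages[, 1]), c(2L, 1L, 0L))
  # irreconcilable pair goes to the conflict list
  p4 <- panel_from_dosages(matrix(1L, 3), "A", "G", dataset = "D4",
                           locus_ids = "l1")
  pA <- panel_from_dosages(matrix(1L, 3, 2), "A", "C",
                           locus_ids = c("l1", "l2"))
  pB <- panel_from_dosages(matrix(1L, 3, 2), c("A", "A"), c("G", "C"),
                           dataset = "D5", locus_ids = c("l1", "l2"))
  out3 <- intersect_panels(list(pA, pB))
  expect_identical(out3$conflicts, "l1")
  expect_identical(out3$shared, "l2")
})

test_that("ambiguity classification covers the four pair types", {
  expect_true(is_ambiguous("A", "T"))
  expect_true(is_ambiguous("T", "A"))
  expect_true(is_ambiguous("C", "G"))
  expect_false(is_ambiguous("A", "C"))
  expect_identical(is_ambiguous(c("A", "G", "C"), c("T", "T", "G")),
                   c(TRUE, FALSE, TRUE))
})

test_that("allele_frequency counts the designated allele among calls", {
  p <- panel_from_dosages(matrix(c(0L, 0L, 0L, 0L), 4), "A", "C")
  expect_equal(allele_frequency(p, "LOC1", "L001")$freq, 0)
  p2 <- panel_from_dosages(matrix(c(2L, 2L, NA), 3), "A", "C")
  af <- allele_frequency(p2, "LOC1", "L001")
  expect_equal(af$freq, 1)
  expect_equal(af$n_called, 2)
  p3 <- panel_from_dosages(matrix(c(0L, 1L, 1L, 2L), 4), "A", "C")
  expect_equal(allele_frequency(p3, "LOC1", "L001")$freq, 0.5)
  # zero calls propagate as NA, not an error
  p4 <- panel_from_dosages(matrix(NA_integer_, 2), "A", "C")
  expect_true(is.na(allele_frequency(p4, "LOC1", "L001")$freq))
})

test_that("calibration reproduces a hand-enumerated error curve", {
  # one locale; reference MAFs 0.10/0.20/0.30/0.40; alternate frequencies of
  # the same allele 0.12/0.21/0.78/0.41: only the 0.78 locus mismatches
  fx <- two_panel_fixture(rbind(c(0.10, 0.20, 0.30, 0.40)),
                          rbind(c(0.12, 0.21, 0.78, 0.41)),
                          n = 50, allele1 = "A", allele2 = "C")
  cal <- calibrate_strand_threshold(fx$pairs, fx$panels,
                                    colnames(fx$panels$REF$dosages))
  err <- cal$error_rate[1, ]
  expect_true(is.na(err[["0.05"]]))          # empty cumulative bin
  expect_equal(err[["0.10"]], 0)             # {0.10}
  expect_equal(err[["0.30"]], 1 / 3)         # {0.10, 0.20, 0.30}
  expect_equal(err[["0.40"]], 1 / 4)
  expect_equal(err[["0.45"]], 1 / 4)
  expect_equal(cal$confidence[1, "0.45"], 0.75)
  expect_equal(cal$n_binned[1, "0.45"], 4)
})

test_that("calibration selects the grid maximum on perfectly matched data", {
  set.seed(71)
  f <- rbind(round(runif(200, 0.02, 0.48) * 100) / 100)
  fx3 <- lapply(1:3, function(k) {
    f_k <- rbind(round(runif(200, 0.02, 0.48) * 100) / 100)
    f_k
  })
  f_ref <- do.call(rbind, fx3)
  fx <- two_panel_fixture(f_ref, f_ref, n = 50, allele1 = "A",
                          allele2 = "C", n_locales = 3)
  cal <- calibrate_strand_threshold(fx$pairs, fx$panels,
                                    colnames(fx$panels$REF$dosages))
  expect_equal(cal$selected_threshold, 0.45)
  expect_equal(unname(cal$mean_confidence[length(cal$grid)]), 1)
})

test_that("total mismatch selects no threshold at all", {
  f_ref <- rbind(c(0.10, 0.20, 0.30, 0.40))
  fx <- two_panel_fixture(f_ref, 1 - f_ref, n = 50, allele1 = "A",
                          allele2 = "C")
  cal <- calibrate_strand_threshold(fx$pairs, fx$panels,
                                    colnames(fx$panels$REF$dosages))
  expect_true(is.na(cal$selected_threshold))
  expect_equal(unname(cal$confidence[1, "0.45"]), 0)
})

test_that("calibration is order-insensitive and monotone in the requirement", {
  set.seed(72)
  f_ref <- rbind(round(runif(60, 0.02, 0.48) * 100) / 100)
  f_alt <- f_ref
  f_alt[, 1:6] <- 1 - f_alt[, 1:6]  # a few mismatches
  fx <- two_panel_fixture(f_ref, f_alt, n = 50, allele1 = "A",
                          allele2 = "C")
  ids <- colnames(fx$panels$REF$dosages)
  cal1 <- calibrate_strand_threshold(fx$pairs, fx$panels, ids)
  cal2 <- calibrate_strand_threshold(fx$pairs, fx$panels, rev(ids))
  expect_equal(cal1$error_rate, cal2$error_rate)
  expect_equal(cal1$selected_threshold, cal2$selected_threshold)
  reqs <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  sel <- vapply(reqs, function(cr)
    calibrate_strand_threshold(fx$pairs, fx$panels, ids,
                               confidence_requirement = cr)$selected_threshold,
    numeric(1))
  sel[is.na(sel)] <- -Inf
  expect_true(all(diff(sel) <= 0))
})

test_that("strand resolution applies the threshold rule per locale", {
  # 3 locales, 3 ambiguous loci: clear flip, clear match, in-band
  f_ref <- rbind(c(0.10, 0.10, 0.48), c(0.10, 0.10, 0.48),
                 c(0.10, 0.12, 0.50))
  f_alt <- rbind(c(0.90, 0.12, 0.10), c(0.90, 0.10, 0.52),
                 c(0.88, 0.10, 0.90))
  fx <- two_panel_fixture(f_ref, f_alt, n = 50, allele1 = "A",
                          allele2 = "T", n_locales = 3)
  res <- resolve_ambiguous_strands(fx$pairs, fx$panels,
                                   colnames(fx$panels$REF$dosages), 0.45)
  tab <- res$table
  expect_identical(tab$decision, c("FLIP", "KEEP_AS_IS", "DISCARD"))
  expect_identical(res$datasets_to_flip, "ALT")
  # mixed verdicts discard under the strict consensus
  f_alt2 <- rbind(c(0.90), c(0.10), c(0.90))
  f_ref2 <- rbind(c(0.10), c(0.10), c(0.10))
  fx2 <- two_panel_fixture(f_ref2, f_alt2, n = 50, allele1 = "C",
                           allele2 = "G", n_locales = 3)
  res2 <- resolve_ambiguous_strands(fx2$pairs, fx2$panels, "L001", 0.45)
  expect_identical(res2$table$decision, "DISCARD")
  # ... but a 2-vs-1 majority flips under the relaxed consensus
  res3 <- resolve_ambiguous_strands(fx2$pairs, fx2$panels, "L001", 0.45,
                                    consensus = "majority")
  expect_identical(res3$table$decision, "FLIP")
  # calling it on a non-ambiguous locus is a contract error
  fx3 <- two_panel_fixture(rbind(0.1), rbind(0.9), n = 10, allele1 = "A",
                           allele2 = "C")
  expect_error(resolve_ambiguous_strands(fx3$pairs, fx3$panels, "L001",
                                         0.45), "non-ambiguous")
})

test_that("missingness rules fire exactly at their published boundaries", {
  # 10 locations x 10 individuals; locus 1: call rate exactly 0.60 in one
  # location (rule A, <=); locus 2: 20% missing in exactly 6 locations
  # (rule B, > 5); locus 3: 20% missing in exactly 5 locations (retained);
  # locus 4: fully typed (retained)
  n_loc <- 10; n_per <- 10
  dos <- array(1L, c(n_loc * n_per, 4))
  loc_of <- rep(seq_len(n_loc), each = n_per)
  dos[loc_of == 1, 1][1:4] <- NA          # call rate 0.6 at location 1
  for (l in 1:6) dos[loc_of == l, 2][1:2] <- NA  # 20% missing, 6 locations
  for (l in 1:5) dos[loc_of == l, 3][1:2] <- NA  # 20% missing, 5 locations
  p <- panel_from_dosages(dos, "A", "C",
                          locations = sprintf("S%02d", loc_of))
  out <- filter_missingness(p)
  expect_setequal(out$discard, c("L001", "L002"))
  expect_identical(out$events$rule_id[out$events$locus_id == "L001"],
                   "MISSINGNESS_A")
  expect_identical(out$events$rule_id[out$events$locus_id == "L002"],
                   "MISSINGNESS_B")
  # call rate just above the floor is retained
  dos2 <- array(1L, c(10, 1))
  dos2[1:3] <- NA  # call rate 0.7 > 0.6
  p2 <- panel_from_dosages(dos2, "A", "C")
  expect_length(filter_missingness(p2)$discard, 0)
})

test_that("relaxing the call-rate floor never discards more loci", {
  for (seed in 1:5) {
    p <- random_panel(seed + 100, n_loci = 30, n_locs = 4, n_per = 8,
                      missing_rate = 0.3)
    floors <- c(0.8, 0.6, 0.4, 0.2)
    ns <- vapply(floors, function(fl)
      length(filter_missingness(p, call_rate_floor = fl)$discard),
      numeric(1))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("HWE filter discards at more than three aberrant locations", {
  set.seed(81)
  n_loc <- 10; n <- 30; L <- 50
  base <- function() {
    m <- matrix(rbinom(n_loc * n * L, 2, 0.5), n_loc * n, L)
    storage.mode(m) <- "integer"
    m
  }
  mk <- function(n_aberrant) {
    dos <- base()
    loc_of <- rep(seq_len(n_loc), each = n)
    for (l in seq_len(n_aberrant)) dos[loc_of == l, 1] <- 1L  # all het
    panel_from_dosages(dos, "A", "C",
                       locations = sprintf("S%02d", loc_of))
  }
  out4 <- hwe_filter(mk(4))
  expect_identical(out4$discard, "L001")
  expect_equal(out4$n_tests, n_loc * L)
  out3 <- hwe_filter(mk(3))
  expect_length(out3$discard, 0)
})

test_that("replicate FST overlap rule matches the hand example", {
  sets <- list(p1 = sprintf("l%d", 1:5), p2 = sprintf("l%d", 4:8),
               p3 = sprintf("l%d", 96:100))
  expect_identical(snpharmony:::replicate_overlap_discard(sets, 1),
                   c("l4", "l5"))
  expect_identical(snpharmony:::replicate_overlap_discard(sets["p1"], 1),
                   character(0))
})

test_that("identical replicate samples yield no replicate-FST discards", {
  set.seed(82)
  f <- rbind(round(runif(40, 0.1, 0.9) * 100) / 100,
             round(runif(40, 0.1, 0.9) * 100) / 100)
  fx <- two_panel_fixture(f, f, n = 50, allele1 = "A", allele2 = "C",
                          n_locales = 2)
  ids <- colnames(fx$panels$REF$dosages)
  out <- replicate_fst_screen(fx$pairs, fx$panels, ids)
  # identical samples: all theta <= 0, so the elevated-divergence sets are
  # empty and nothing can overlap
  expect_true(all(out$theta <= 0, na.rm = TRUE))
  expect_length(out$discard, 0)
  # a single pair can never reach "more than one replicate"
  out1 <- replicate_fst_screen(fx$pairs[1, ], fx$panels, ids)
  expect_length(out1$discard, 0)
})

test_that("few defined-FST loci triggers the quantile-instability warning", {
  f <- rbind(c(0.2, 0.4, 0.6))
  fx <- two_panel_fixture(f, f, n = 20, allele1 = "A", allele2 = "C")
  expect_warning(
    replicate_fst_screen(fx$pairs, fx$panels,
                         colnames(fx$panels$REF$dosages)),
    "quantile unstable")
})

test_that("a clean idealized run retains every shared locus", {
  # island model with weak divergence and MAF <= 0.25 keeps every sampled
  # frequency conclusively out of the inconclusive band; identical
  # replicate draws remove sampling noise from the comparability checks
  cfg <- sim_config(seed = 91, n_loci = 300, n_populations = 6,
                    n_datasets = 2, per_pop_n = 40, frac_flipped = 0,
                    missing_rate = 0, replicate_locales = 2,
                    fst_divergence = 0.005, structure = "island",
                    ancestral_maf_range = c(0.05, 0.25),
                    n_private_loci = 5, replicate_identical = TRUE)
  sim <- emit_datasets(cfg)
  res <- run_harmonization(sim$panels, sim$pairs)
  expect_equal(unname(res$summary["n_retained"]),
               unname(res$summary["n_shared"]))
  expect_equal(unname(res$summary["n_flipped"]), 0)
  expect_identical(unique(res$ledger$status$status), "RETAINED")
})

test_that("the full run recovers injected flips and keeps the ledger closed", {
  for (seed in c(101, 102, 103)) {
    cfg <- sim_config(seed = seed, n_loci = 400, n_populations = 9,
                      n_datasets = 3, per_pop_n = 40, n_private_loci = 10)
    sim <- emit_datasets(cfg)
    res <- run_harmonization(sim$panels, sim$pairs)
    truth_flips <- unique(sim$truth$flips$locus_id)
    dec <- res$resolution$table
    dec_truth <- dec$decision[dec$locus_id %in% truth_flips]
    expect_length(dec_truth, length(truth_flips))
    expect_false(any(dec_truth == "KEEP_AS_IS"))
    # no spurious flip decisions
    expect_length(setdiff(dec$locus_id[dec$decision == "FLIP"],
                          truth_flips), 0)
    # conservation: every shared locus has exactly one final status
    expect_equal(nrow(res$ledger$status),
                 unname(res$summary["n_shared"]))
    expect_equal(sum(res$ledger$status$status == "RETAINED") +
                   sum(res$ledger$status$status == "DISCARDED"),
                 unname(res$summary["n_shared"]))
    # flip correctness: corrected replicate frequencies agree with the
    # reference within binomial sampling error (the 4*sqrt(pq/2n) band is
    # ~2.8 sd of the frequency difference, so a ~0.5% exceedance rate is
    # expected from sampling alone)
    p <- res$panel
    inside <- numeric(0)
    for (k in seq_len(nrow(sim$pairs))) {
      fr <- location_freqs(p, sim$pairs$location_ref[k])
      fa <- location_freqs(p, sim$pairs$location_alt[k])
      d <- abs(fr$freq - fa$freq)
      bound <- 4 * sqrt(pmax(fr$freq * (1 - fr$freq), 0.05) /
                          (2 * pmax(fa$n_called, 1)))
      inside <- c(inside, (d <= bound)[!is.na(d)])
    }
    expect_gt(mean(inside), 0.98)
    # merged panel passes all invariants
    expect_silent(validate_panel(res$panel))
  }
})

test_that("a NONE threshold discards every ambiguous locus with a warning", {
  cfg <- sim_config(seed = 111, n_loci = 150, n_populations = 6,
                    n_datasets = 2, per_pop_n = 25, replicate_locales = 2,
                    n_private_loci = 0)
  sim <- emit_datasets(cfg)
  # poison the unambiguous calibration loci: flip ALL designated-allele
  # frequencies in the alternate dataset so every interval mismatches
  p2 <- sim$panels[[2]]
  unamb <- p2$loci$locus_id[!is_ambiguous(p2$loci)]
  p2$dosages[, unamb] <- 2L - p2$dosages[, unamb]
  sim$panels[[2]] <- p2
  expect_warning(res <- run_harmonization(sim$panels, sim$pairs),
                 "no MAF threshold")
  expect_true(is.na(res$summary[["selected_threshold"]]))
  amb <- sim$truth$loci$locus_id[is_ambiguous(sim$truth$loci)]
  expect_length(intersect(amb, res$panel$loci$locus_id), 0)
})
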