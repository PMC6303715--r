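# Data-synthesis harmonization: panel intersection with designation
# reconciliation, strand-ambiguity calibration against geographic replicate
# pairs, frequency-based flip resolution, and the tiered locus QC
# (missingness rules, HWE with FDR, replicate FST screen), all recorded in
# an audit ledger.

QC_RULES <- c("NOT_SHARED", "MISSINGNESS_A", "MISSINGNESS_B", "HWE_MULTI",
              "REPL_FST", "STRAND_DISCARD")

#' Harmonization configuration
#'
#' Thresholds of the tiered QC and the strand-calibration rule. Defaults are
#' the published procedure: calibration on cumulative 0.05 MAF intervals up
#' to 0.45 with a 0.95 confidence requirement (mean over locales >= 0.95 and
#' each locale strictly > 0.95); a locus is discarded when <= 60% of its
#' genotypes are called in any sampling location, or when >= 15% are missing
#' in more than five locations; HWE departures are discarded when
#' significant (q <= 0.05 after BH correction across all tests jointly) in
#' more than three locations; and loci in the upper 5% of per-locus
#' replicate FST in more than one replicate pair are discarded.
#'
#' @param confidence_requirement locale confidence rule, default 0.95.
#' @param grid cumulative MAF interval endpoints.
#' @param call_rate_floor,missing_ceiling,max_bad_samples missingness rules.
#' @param hwe_q,hwe_max_samples,hwe_min_called HWE rule.
#' @param fst_quantile,fst_max_pairs replicate FST screen.
#' @param reference_dataset dataset whose strand designations are taken as
#'   reference (default: dataset of the first panel).
#' @param consensus `"strict"` (all locale verdicts conclusive and
#'   identical) or `"majority"` (majority of conclusive verdicts).
#' @param stage_order `"strand_first"` (default: calibrate and correct
#'   strands, then run the QC filters on the corrected panels -- an
#'   uncorrected flip would otherwise inflate replicate FST and be consumed
#'   by the outlier screen instead of being corrected) or `"qc_first"`
#'   (filters first, strand resolution restricted to the retained loci).
#' @return a `harmonization_config` list.
#' @export
harmonization_config <- function(confidence_requirement = 0.95,
                                 grid = seq(0.05, 0.45, by = 0.05),
                                 call_rate_floor = 0.60,
                                 missing_ceiling = 0.15,
                                 max_bad_samples = 5,
                                 hwe_q = 0.05,
                                 hwe_max_samples = 3,
                                 hwe_min_called = 2,
                                 fst_quantile = 0.95,
                                 fst_max_pairs = 1,
                                 reference_dataset = NULL,
                                 consensus = c("strict", "majority"),
                                 stage_order = c("strand_first", "qc_first")) {
  cfg <- list(confidence_requirement = confidence_requirement, grid = grid,
              call_rate_floor = call_rate_floor,
              missing_ceiling = missing_ceiling,
              max_bad_samples = max_bad_samples,
              hwe_q = hwe_q, hwe_max_samples = hwe_max_samples,
              hwe_min_called = hwe_min_called,
              fst_quantile = fst_quantile, fst_max_pairs = fst_max_pairs,
              reference_dataset = reference_dataset,
              consensus = match.arg(consensus),
              stage_order = match.arg(stage_order))
  rates <- c(cfg$confidence_requirement, cfg$call_rate_floor,
             cfg$missing_ceiling, cfg$hwe_q, cfg$fst_quantile)
  if (any(rates < 0 | rates > 1)) stop("thresholds must lie in [0, 1]")
  class(cfg) <- "harmonization_config"
  cfg
}

#' Replicate-pair table constructor
#'
#' A geographic replicate pair is the same biological population sampled
#' independently in two datasets; it anchors the cross-dataset
#' comparability checks (strand calibration and the replicate FST screen).
#'
#' @param locale locale names.
#' @param location_ref,dataset_ref sample in the reference dataset.
#' @param location_alt,dataset_alt sample in the other dataset.
#' @return data frame with one row per pair.
#' @export
replicate_pairs <- function(locale, location_ref, dataset_ref,
                            location_alt, dataset_alt) {
  df <- data.frame(locale = locale, location_ref = location_ref,
                   dataset_ref = dataset_ref, location_alt = location_alt,
                   dataset_alt = dataset_alt, stringsAsFactors = FALSE)
  if (any(df$dataset_ref == df$dataset_alt))
    stop("the two members of a replicate pair must come from ",
         "different datasets")
  df
}

# Ledger event rows; returns a 0-row frame when ids is empty.
ledger_events <- function(ids, rule_id, detail) {
  n <- length(ids)
  data.frame(locus_id = ids, rule_id = rep(rule_id, n),
             outcome = rep("FAIL", n), detail = rep_len(detail, n),
             stringsAsFactors = FALSE)
}

# Panel containing a (location, dataset) sample; panels is a named list by
# dataset name.
panel_of <- function(panels, dataset, location) {
  p <- panels[[dataset]]
  if (is.null(p)) stop("no panel for dataset ", dataset)
  if (!location %in% p$samples$location_code)
    stop("location ", location, " absent from dataset ", dataset)
  p
}

#' Intersect panels and reconcile allele designations
#'
#' Computes the locus ids common to all panels and reconciles each panel's
#' allele pair against the first (reference) panel: reversed pairs have
#' their designation swapped (dosage recoded g -> 2 - g); pairs that are the
#' reverse complement of the reference are relabelled to the reference
#' strand (with a designation swap where needed). Unambiguous pairs that
#' cannot be reconciled this way are moved to a conflict list and excluded
#' from the shared set. Loci with an unknown second allele are matched on
#' the known allele.
#'
#' @param panels list of two or more `genotype_panel` objects.
#' @return list with `shared` (locus ids, reference-panel order), `private`
#'   (per-panel ids absent from some panel), `conflicts` (irreconcilable
#'   ids), and `panels` (the reconciled panels, designations aligned).
#' @export
intersect_panels <- function(panels) {
  if (length(panels) < 2) stop("intersect_panels needs >= 2 panels")
  id_sets <- lapply(panels, function(p) p$loci$locus_id)
  shared <- Reduce(intersect, id_sets)
  if (length(shared) == 0) stop("synthesis error: zero shared loci")
  private <- lapply(id_sets, function(ids) setdiff(ids, shared))
  conflicts <- character(0)
  ref <- panels[[1]]
  ridx <- match(shared, ref$loci$locus_id)
  ra1 <- ref$loci$allele1[ridx]; ra2 <- ref$loci$allele2[ridx]
  for (k in seq_along(panels)[-1]) {
    p <- panels[[k]]
    pidx <- match(shared, p$loci$locus_id)
    b1 <- p$loci$allele1[pidx]; b2 <- p$loci$allele2[pidx]
    swap_ids <- character(0)
    for (s in seq_along(shared)) {
      A <- c(ra1[s], ra2[s]); B <- c(b1[s], b2[s])
      Bc <- unname(COMPLEMENT[B])
      if (is.na(B[2])) {  # single known allele: match by identity or
        # complement and complete the pair from the reference panel
        if (B[1] == A[1]) {
          p$loci$allele2[pidx[s]] <- A[2]
        } else if (!is.na(A[2]) && B[1] == A[2]) {
          p$loci$allele2[pidx[s]] <- A[1]
          swap_ids <- c(swap_ids, shared[s])
        } else if (Bc[1] == A[1]) {
          p$loci$allele1[pidx[s]] <- A[1]
          p$loci$allele2[pidx[s]] <- A[2]
        } else if (!is.na(A[2]) && Bc[1] == A[2]) {
          p$loci$allele1[pidx[s]] <- A[2]
          p$loci$allele2[pidx[s]] <- A[1]
          swap_ids <- c(swap_ids, shared[s])
        } else conflicts <- c(conflicts, shared[s])
        next
      }
      if (identical(B, A)) next
      if (identical(B, A[c(2, 1)])) {
        swap_ids <- c(swap_ids, shared[s])
      } else if (identical(Bc, A)) {
        p$loci$allele1[pidx[s]] <- A[1]
        p$loci$allele2[pidx[s]] <- A[2]
      } else if (identical(Bc, A[c(2, 1)])) {
        p$loci$allele1[pidx[s]] <- A[2]
        p$loci$allele2[pidx[s]] <- A[1]
        swap_ids <- c(swap_ids, shared[s])
      } else {
        conflicts <- c(conflicts, shared[s])
      }
    }
    p <- swap_designation(p, swap_ids)
    panels[[k]] <- p
  }
  conflicts <- unique(conflicts)
  shared <- setdiff(shared, conflicts)
  if (length(shared) == 0) stop("synthesis error: zero shared loci after ",
                                "allele-pair reconciliation")
  list(shared = shared, private = private, conflicts = conflicts,
       panels = panels)
}

# Designated-allele frequencies at both members of each replicate pair.
# Returns list of per-pair lists: f_ref, f_alt, n_ref, n_alt (vectors over
# locus_ids).
pair_frequencies <- function(pairs, panels, locus_ids) {
  lapply(seq_len(nrow(pairs)), function(k) {
    pr <- panel_of(panels, pairs$dataset_ref[k], pairs$location_ref[k])
    pa <- panel_of(panels, pairs$dataset_alt[k], pairs$location_alt[k])
    fr <- location_freqs(pr, pairs$location_ref[k], locus_ids)
    fa <- location_freqs(pa, pairs$location_alt[k], locus_ids)
    list(locale = pairs$locale[k], f_ref = fr$freq, f_alt = fa$freq,
         n_ref = fr$n_called, n_alt = fa$n_called)
  })
}

#' Calibrate the MAF threshold for strand resolution
#'
#' Ground-truths frequency-based strand matching on the unambiguous shared
#' loci, where the strand is known from allele identities. At each replicate
#' locale, loci are binned by the reference sample's minor allele frequency
#' into cumulative 0.05 intervals (MAF <= x for x on the grid); the error
#' rate at x is the fraction of binned loci whose frequency of that same
#' (reference-minor) allele exceeds 0.5 in the other dataset, i.e. loci a
#' frequency comparison would mis-orient. Confidence is 1 - error rate;
#' locale confidences are averaged. The selected threshold is the largest
#' grid value whose mean confidence meets `confidence_requirement` and whose
#' per-locale confidence strictly exceeds it at every locale; `NA` when no
#' grid value qualifies.
#'
#' @param pairs replicate-pair table ([replicate_pairs()]).
#' @param panels named list of `genotype_panel` objects (names = dataset).
#' @param locus_ids unambiguous shared loci to calibrate on.
#' @param confidence_requirement default 0.95.
#' @param grid cumulative MAF interval endpoints, default 0.05..0.45.
#' @return a `strand_calibration`: list with `grid`, `error_rate` and
#'   `confidence` (locale x grid matrices), `n_binned`, `mean_confidence`,
#'   `selected_threshold`, `confidence_requirement`.
#' @export
calibrate_strand_threshold <- function(pairs, panels, locus_ids,
                                       confidence_requirement = 0.95,
                                       grid = seq(0.05, 0.45, by = 0.05)) {
  if (nrow(pairs) < 1) stop("need at least one replicate pair")
  if (length(locus_ids) < 1) stop("need at least one unambiguous locus")
  pf <- pair_frequencies(pairs, panels, locus_ids)
  nloc <- length(pf)
  err <- conf <- nbin <- matrix(NA_real_, nloc, length(grid),
                                dimnames = list(pairs$locale,
                                                sprintf("%.2f", grid)))
  for (k in seq_len(nloc)) {
    f_ref <- pf[[k]]$f_ref; f_alt <- pf[[k]]$f_alt
    ok <- !is.na(f_ref) & !is.na(f_alt)
    maf_ref <- pmin(f_ref[ok], 1 - f_ref[ok])
    # frequency, in the alternate dataset, of the allele that is minor in
    # the reference sample
    f_alt_minor <- ifelse(f_ref[ok] <= 0.5, f_alt[ok], 1 - f_alt[ok])
    mismatch <- f_alt_minor > 0.5
    for (g in seq_along(grid)) {
      inbin <- maf_ref <= grid[g]
      nbin[k, g] <- sum(inbin)
      if (any(inbin)) {
        err[k, g] <- sum(mismatch[inbin]) / sum(inbin)
        conf[k, g] <- 1 - err[k, g]
      }
    }
  }
  if (all(is.na(err)))
    stop("calibration error: empty bin at every grid value")
  mean_conf <- colMeans(conf)
  eligible <- !is.na(mean_conf) &
    mean_conf >= confidence_requirement &
    apply(conf, 2, function(co) all(!is.na(co) & co > confidence_requirement))
  selected <- if (any(eligible)) max(grid[eligible]) else NA_real_
  structure(list(grid = grid, error_rate = err, confidence = conf,
                 n_binned = nbin, mean_confidence = mean_conf,
                 selected_threshold = selected,
                 confidence_requirement = confidence_requirement),
            class = "strand_calibration")
}

#' @export
print.strand_calibration <- function(x, ...) {
  cat("<strand_calibration> grid ", min(x$grid), "..", max(x$grid),
      "; selected threshold: ",
      if (is.na(x$selected_threshold)) "NONE" else x$selected_threshold,
      "\n", sep = "")
  mc <- x$mean_confidence
  cat("  mean confidence at grid max: ",
      ifelse(is.na(mc[length(mc)]), "NA",
             sprintf("%.4f", mc[length(mc)])), "\n", sep = "")
  invisible(x)
}

#' Resolve strand orientation of ambiguous loci
#'
#' Applies the calibrated frequency rule at every replicate locale: with
#' threshold t, a locus is MATCHED when the designated-allele frequency is
#' on the same side of the (t, 1 - t) band in both datasets, FLIPPED when on
#' opposite sides, and INCONCLUSIVE when either frequency falls inside the
#' band \[t, 1 - t\] or is undefined. The final decision requires a
#' consistent consensus: FLIP only when every locale verdict is FLIPPED,
#' KEEP_AS_IS only when every verdict is MATCHED, otherwise DISCARD (with
#' `consensus = "majority"`, a majority of conclusive verdicts decides).
#' A FLIP is applied to every non-reference dataset.
#'
#' @param pairs replicate-pair table.
#' @param panels named list of panels.
#' @param locus_ids ambiguous shared loci.
#' @param threshold calibrated MAF threshold (not `NA`).
#' @param consensus `"strict"` or `"majority"`.
#' @return a `strand_resolution`: list with `table` (locus_id, one verdict
#'   column per locale, `decision`), `datasets_to_flip`, `threshold`.
#' @export
resolve_ambiguous_strands <- function(pairs, panels, locus_ids, threshold,
                                      consensus = c("strict", "majority")) {
  consensus <- match.arg(consensus)
  if (is.na(threshold)) stop("threshold is NONE; cannot resolve strands")
  if (length(locus_ids) == 0) {
    return(structure(list(
      table = data.frame(locus_id = character(0),
                         decision = character(0)),
      datasets_to_flip = character(0), threshold = threshold),
      class = "strand_resolution"))
  }
  for (p in panels) {
    idx <- match(locus_ids, p$loci$locus_id)
    hit <- !is.na(idx)
    if (any(hit) && !all(is_ambiguous(p$loci[idx[hit], , drop = FALSE])))
      stop("resolve_ambiguous_strands called on a non-ambiguous locus")
  }
  pf <- pair_frequencies(pairs, panels, locus_ids)
  t <- threshold
  verdicts <- vapply(pf, function(q) {
    low_r <- q$f_ref < t; high_r <- q$f_ref > 1 - t
    low_a <- q$f_alt < t; high_a <- q$f_alt > 1 - t
    v <- rep("INCONCLUSIVE", length(locus_ids))
    v[(low_r & low_a) | (high_r & high_a)] <- "MATCHED"
    v[(low_r & high_a) | (high_r & low_a)] <- "FLIPPED"
    v[is.na(q$f_ref) | is.na(q$f_alt)] <- "INCONCLUSIVE"
    v
  }, character(length(locus_ids)))
  verdicts <- matrix(verdicts, nrow = length(locus_ids),
                     dimnames = list(locus_ids, pairs$locale))
  decide_strict <- function(v) {
    if (all(v == "FLIPPED")) "FLIP"
    else if (all(v == "MATCHED")) "KEEP_AS_IS"
    else "DISCARD"
  }
  decide_majority <- function(v) {
    v <- v[v != "INCONCLUSIVE"]
    if (length(v) == 0) return("DISCARD")
    nf <- sum(v == "FLIPPED"); nm <- sum(v == "MATCHED")
    if (nf > nm) "FLIP" else if (nm > nf) "KEEP_AS_IS" else "DISCARD"
  }
  decision <- apply(verdicts, 1,
                    if (consensus == "strict") decide_strict
                    else decide_majority)
  ref_ds <- unique(pairs$dataset_ref)
  structure(list(
    table = data.frame(locus_id = locus_ids,
                       as.data.frame(verdicts, stringsAsFactors = FALSE,
                                     row.names = NULL),
                       decision = unname(decision),
                       stringsAsFactors = FALSE),
    datasets_to_flip = setdiff(names(panels), ref_ds),
    threshold = threshold), class = "strand_resolution")
}

#' @export
print.strand_resolution <- function(x, ...) {
  tab <- table(factor(x$table$decision,
                      levels = c("KEEP_AS_IS", "FLIP", "DISCARD")))
  cat("<strand_resolution> threshold ", x$threshold, ": ",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Per-(locus, location) call-rate matrix over all panels' locations.
call_rate_matrix <- function(panels, locus_ids) {
  mats <- lapply(panels, function(p) {
    d <- p$dosages[, locus_ids, drop = FALSE]
    loc <- p$individuals$location_code
    n <- rowsum((!is.na(d)) + 0L, loc)
    tot <- as.vector(table(loc)[rownames(n)])
    n / tot
  })
  do.call(rbind, mats)  # locations x loci
}

#' Missing-data locus filter
#'
#' Two published rules, applied per (locus, sampling location): rule A
#' discards a locus if its call rate is at or below `call_rate_floor`
#' (default 60%) in any location; rule B discards it if the missing fraction
#' is at or above `missing_ceiling` (default 15%) in more than
#' `max_bad_samples` (default 5) locations.
#'
#' @param panels a `genotype_panel` or list of panels.
#' @param locus_ids loci to evaluate (default: all loci of the first panel).
#' @param call_rate_floor,missing_ceiling,max_bad_samples rule thresholds.
#' @return list with `discard` (locus ids) and `events` (ledger rows:
#'   `locus_id`, `rule_id`, `outcome`, `detail`).
#' @export
filter_missingness <- function(panels, locus_ids = NULL,
                               call_rate_floor = 0.60,
                               missing_ceiling = 0.15,
                               max_bad_samples = 5) {
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  if (is.null(locus_ids)) locus_ids <- panels[[1]]$loci$locus_id
  cr <- call_rate_matrix(panels, locus_ids)
  rule_a <- colSums(cr <= call_rate_floor) > 0
  n_bad <- colSums((1 - cr) >= missing_ceiling)
  rule_b <- n_bad > max_bad_samples
  ids_a <- locus_ids[rule_a]
  ids_b <- locus_ids[rule_b & !rule_a]
  events <- rbind(
    ledger_events(ids_a, "MISSINGNESS_A",
                  paste0("call rate <= ", call_rate_floor,
                         " in >= 1 location")),
    ledger_events(ids_b, "MISSINGNESS_B",
                  if (length(ids_b)) paste0("missing >= ", missing_ceiling,
                                            " in ", n_bad[rule_b & !rule_a],
                                            " locations") else character(0)))
  list(discard = locus_ids[rule_a | rule_b], events = events)
}

#' HWE locus filter with joint FDR correction
#'
#' Tests Hardy-Weinberg equilibrium exactly at every (locus, location) with
#' at least `hwe_min_called` called individuals, applies Benjamini-Hochberg
#' FDR correction jointly across *all* tests, and discards a locus when
#' q <= `alpha_q` in more than `max_sig_samples` locations.
#'
#' @param panels a `genotype_panel` or list of panels.
#' @param locus_ids loci to evaluate.
#' @param alpha_q FDR significance level, default 0.05.
#' @param max_sig_samples discard when significant in more than this many
#'   locations, default 3.
#' @param min_called minimum called individuals for a test (skipped and
#'   recorded otherwise).
#' @return list with `discard`, `events`, `tests` (per-test table with
#'   `locus_id`, `location_code`, `p`, `q`), `n_tests`, `n_skipped`.
#' @export
hwe_filter <- function(panels, locus_ids = NULL, alpha_q = 0.05,
                       max_sig_samples = 3, min_called = 2) {
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  if (is.null(locus_ids)) locus_ids <- panels[[1]]$loci$locus_id
  rows <- list()
  for (p in panels) {
    cnt <- genotype_counts(p, intersect(locus_ids, p$loci$locus_id))
    for (loc in rownames(cnt$n2)) {
      rows[[length(rows) + 1]] <- data.frame(
        locus_id = colnames(cnt$n2), location_code = loc,
        n2 = cnt$n2[loc, ], n1 = cnt$n1[loc, ], n0 = cnt$n0[loc, ],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  tests <- do.call(rbind, rows)
  n_called <- tests$n2 + tests$n1 + tests$n0
  skip <- n_called < min_called
  tests$p <- NA_real_
  tests$p[!skip] <- hwe_exact_batch(tests$n2[!skip], tests$n1[!skip],
                                    tests$n0[!skip])
  tests$q <- NA_real_
  tests$q[!skip] <- bh_fdr(tests$p[!skip])
  sig <- !skip & tests$q <= alpha_q
  n_sig <- tapply(sig, tests$locus_id, sum)
  bad <- names(n_sig)[n_sig > max_sig_samples]
  events <- ledger_events(
    bad, "HWE_MULTI",
    if (length(bad)) paste0("q <= ", alpha_q, " in ", n_sig[bad],
                            " locations (> ", max_sig_samples, ")")
    else character(0))
  list(discard = bad, events = events,
       tests = tests[, c("locus_id", "location_code", "p", "q")],
       n_tests = sum(!skip), n_skipped = sum(skip))
}

# Overlap rule of the replicate FST screen, separated for testability:
# given per-pair top sets, discard loci appearing in more than max_pairs.
replicate_overlap_discard <- function(top_sets, max_pairs = 1) {
  counts <- table(unlist(top_sets))
  sort(names(counts)[counts > max_pairs])
}

#' Replicate FST outlier screen
#'
#' For each geographic replicate pair, computes per-locus Weir-Cockerham
#' theta between the two samples and takes the loci at or above the
#' `quantile` (default 95th percentile, linear-interpolation definition)
#' among loci with defined and positive theta -- an elevated-divergence
#' screen; non-positive estimates cannot be outliers. A locus is discarded
#' when it falls in that upper set for more than `max_pairs_allowed` pairs.
#'
#' @param pairs replicate-pair table.
#' @param panels named list of panels.
#' @param locus_ids loci to evaluate.
#' @param quantile upper-tail cut, default 0.95.
#' @param max_pairs_allowed default 1.
#' @return list with `discard`, `events`, `top_sets` (per-pair locus sets),
#'   `theta` (loci x pairs matrix), `warnings`.
#' @export
replicate_fst_screen <- function(pairs, panels, locus_ids,
                                 quantile = 0.95, max_pairs_allowed = 1) {
  top_sets <- list()
  warns <- character(0)
  theta_mat <- matrix(NA_real_, length(locus_ids), nrow(pairs),
                      dimnames = list(locus_ids, pairs$locale))
  for (k in seq_len(nrow(pairs))) {
    pr <- panel_of(panels, pairs$dataset_ref[k], pairs$location_ref[k])
    pa <- panel_of(panels, pairs$dataset_alt[k], pairs$location_alt[k])
    two <- merge_panels(list(
      subset_panel(pr, locus_ids, pairs$location_ref[k]),
      subset_panel(pa, locus_ids, pairs$location_alt[k])), locus_ids)
    pl <- pair_wc(two, pairs$location_ref[k], pairs$location_alt[k])
    th <- stats::setNames(pl$theta, pl$locus_id)
    theta_mat[, k] <- th[locus_ids]
    defined <- th[!is.na(th)]
    if (length(defined) < 20) {
      warns <- c(warns, paste0("pair ", pairs$locale[k], ": only ",
                               length(defined),
                               " loci with defined FST; quantile unstable"))
    }
    if (length(defined) == 0) {
      top_sets[[pairs$locale[k]]] <- character(0)
      next
    }
    top <- upper_quantile_loci(defined, quantile)
    top_sets[[pairs$locale[k]]] <- top[defined[top] > 0]
  }
  discard <- replicate_overlap_discard(top_sets, max_pairs_allowed)
  pair_names <- vapply(discard, function(id)
    paste(names(top_sets)[vapply(top_sets, function(s) id %in% s,
                                 logical(1))], collapse = ","),
    character(1))
  events <- ledger_events(
    discard, "REPL_FST",
    if (length(discard))
      paste0("upper ", sprintf("%d%%", round(100 * (1 - quantile))),
             " FST in pairs: ", pair_names)
    else character(0))
  for (w in warns) warning(w)
  list(discard = discard, events = events, top_sets = top_sets,
       theta = theta_mat, warnings = warns)
}

#' Run the full harmonization pipeline
#'
#' Executes the data-synthesis procedure end to end: panel intersection with
#' designation reconciliation; strand-threshold calibration on the
#' unambiguous shared loci; ambiguous-strand resolution (FLIP applied to
#' every non-reference dataset, DISCARD ledgered); missingness filter; HWE
#' filter with joint FDR correction; replicate FST screen; and the merge of
#' all individuals over the retained, strand-corrected loci (stage order
#' configurable, see [harmonization_config()]). Every shared locus
#' receives exactly one final status in the QC ledger. When calibration
#' selects no threshold, every ambiguous locus is discarded and the run
#' continues with a warning.
#'
#' @param panels list of `genotype_panel` objects (>= 2); names default to
#'   each panel's dataset.
#' @param pairs replicate-pair table ([replicate_pairs()]).
#' @param config a [harmonization_config()].
#' @return a `harmonization_result`: list with `panel` (merged
#'   `genotype_panel`), `ledger` (a `qc_ledger`: `events` + `status`),
#'   `calibration`, `resolution`, and `summary` (named counts).
#' @export
run_harmonization <- function(panels, pairs,
                              config = harmonization_config()) {
  if (length(panels) < 2) stop("run_harmonization needs >= 2 panels")
  if (nrow(pairs) < 1) stop("run_harmonization needs >= 1 replicate pair")
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, function(p) p$samples$dataset[1],
                            character(1))
  ref_ds <- config$reference_dataset
  if (is.null(ref_ds)) ref_ds <- names(panels)[1]
  if (ref_ds != names(panels)[1]) {  # reference panel leads the intersection
    ord <- c(which(names(panels) == ref_ds),
             which(names(panels) != ref_ds))
    panels <- panels[ord]
  }
  events <- list()
  ix <- intersect_panels(panels)
  panels <- ix$panels
  shared <- ix$shared
  if (length(ix$conflicts) > 0)
    events[[length(events) + 1]] <- data.frame(
      locus_id = ix$conflicts, rule_id = "NOT_SHARED", outcome = "FAIL",
      detail = "irreconcilable allele pairs", stringsAsFactors = FALSE)

  ref_loci <- panels[[1]]$loci
  amb <- is_ambiguous(ref_loci[match(shared, ref_loci$locus_id), ])
  amb_ids <- shared[amb]
  unamb_ids <- shared[!amb]

  run_strand <- function(retained_unamb, retained_amb) {
    cal <- calibrate_strand_threshold(
      pairs, panels, retained_unamb,
      confidence_requirement = config$confidence_requirement,
      grid = config$grid)
    if (is.na(cal$selected_threshold)) {
      warning("no MAF threshold met the confidence requirement; ",
              "all ambiguous loci discarded")
      res <- structure(list(
        table = data.frame(locus_id = retained_amb,
                           decision = rep("DISCARD", length(retained_amb)),
                           stringsAsFactors = FALSE),
        datasets_to_flip = setdiff(names(panels), ref_ds),
        threshold = NA_real_), class = "strand_resolution")
    } else {
      res <- resolve_ambiguous_strands(pairs, panels, retained_amb,
                                       cal$selected_threshold,
                                       consensus = config$consensus)
    }
    list(cal = cal, res = res)
  }

  qc_stage <- function(candidate_ids) {
    miss <- filter_missingness(panels, candidate_ids,
                               config$call_rate_floor,
                               config$missing_ceiling,
                               config$max_bad_samples)
    after_miss <- setdiff(candidate_ids, miss$discard)
    hwe <- hwe_filter(panels, after_miss, config$hwe_q,
                      config$hwe_max_samples, config$hwe_min_called)
    after_hwe <- setdiff(after_miss, hwe$discard)
    fst <- replicate_fst_screen(pairs, panels, after_hwe,
                                config$fst_quantile, config$fst_max_pairs)
    list(miss = miss, hwe = hwe, fst = fst,
         retained = setdiff(after_hwe, fst$discard))
  }

  apply_flips <- function(panels, res, ids) {
    for (d in res$datasets_to_flip)
      panels[[d]] <- apply_strand_flip(panels[[d]], ids)
    panels
  }
  if (config$stage_order == "qc_first") {
    qc <- qc_stage(shared)
    st <- run_strand(intersect(qc$retained, unamb_ids),
                     intersect(qc$retained, amb_ids))
    strand_discard <- st$res$table$locus_id[st$res$table$decision ==
                                              "DISCARD"]
    retained <- setdiff(qc$retained, strand_discard)
    flip_ids <- intersect(
      st$res$table$locus_id[st$res$table$decision == "FLIP"], retained)
    panels <- apply_flips(panels, st$res, flip_ids)
  } else {  # strand_first: correct flips before the outlier-sensitive QC
    st <- run_strand(unamb_ids, amb_ids)
    strand_discard <- st$res$table$locus_id[st$res$table$decision ==
                                              "DISCARD"]
    flip_ids <- st$res$table$locus_id[st$res$table$decision == "FLIP"]
    panels <- apply_flips(panels, st$res, flip_ids)
    qc <- qc_stage(setdiff(shared, strand_discard))
    retained <- qc$retained
    flip_ids <- intersect(flip_ids, retained)
  }
  events <- c(events, list(qc$miss$events, qc$hwe$events, qc$fst$events))
  if (length(strand_discard) > 0)
    events[[length(events) + 1]] <- data.frame(
      locus_id = strand_discard, rule_id = "STRAND_DISCARD",
      outcome = "FAIL",
      detail = if (is.na(st$res$threshold)) "no calibrated threshold"
               else "no consistent locale consensus",
      stringsAsFactors = FALSE)

  merged <- merge_panels(panels, retained)
  event_df <- do.call(rbind, events)
  if (is.null(event_df))
    event_df <- data.frame(locus_id = character(0), rule_id = character(0),
                           outcome = character(0), detail = character(0))
  status <- data.frame(
    locus_id = shared,
    status = ifelse(shared %in% retained, "RETAINED", "DISCARDED"),
    stringsAsFactors = FALSE)
  ledger <- structure(list(events = event_df, status = status),
                      class = "qc_ledger")
  summary <- c(
    n_candidate = length(unique(unlist(lapply(panels, function(p)
      p$loci$locus_id)))),
    n_shared = length(shared),
    n_conflict = length(ix$conflicts),
    n_discard_missingness = length(qc$miss$discard),
    n_discard_hwe = length(qc$hwe$discard),
    n_discard_repl_fst = length(qc$fst$discard),
    n_discard_strand = length(strand_discard),
    n_flipped = length(flip_ids),
    n_ambiguous_retained = length(intersect(retained, amb_ids)),
    n_retained = length(retained),
    selected_threshold = unname(st$cal$selected_threshold))
  structure(list(panel = merged, ledger = ledger, calibration = st$cal,
                 resolution = st$res, summary = summary),
            class = "harmonization_result")
}

#' @export
print.harmonization_result <- function(x, ...) {
  s <- x$summary
  cat("<harmonization_result>\n")
  cat("  shared loci:          ", s[["n_shared"]], "\n")
  cat("  discarded missingness:", s[["n_discard_missingness"]], "\n")
  cat("  discarded HWE:        ", s[["n_discard_hwe"]], "\n")
  cat("  discarded repl. FST:  ", s[["n_discard_repl_fst"]], "\n")
  cat("  discarded strand:     ", s[["n_discard_strand"]], "\n")
  cat("  flips applied:        ", s[["n_flipped"]], "\n")
  cat("  retained:             ", s[["n_retained"]],
      " (", s[["n_ambiguous_retained"]], " ambiguous)\n", sep = "")
  cat("  selected threshold:   ",
      if (is.na(s[["selected_threshold"]])) "NONE"
      else s[["selected_threshold"]], "\n")
  invisible(x)
}
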