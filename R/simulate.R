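# Synthetic multi-dataset SNP generator with a recorded truth ledger.
# Emulates the structure of a range-wide data synthesis: several datasets
# genotyping a shared locus core over contiguous geographic blocks of a
# 1-D stepping-stone habitat, geographic replicate sample pairs between the
# reference dataset and the second dataset, strand flips injected at
# ambiguous loci of every non-reference dataset (one shared flip set, as
# when the non-reference datasets come off the same genotyping platform),
# one-sided ascertainment, and dataset-specific missingness.

#' Simulation configuration
#'
#' Defaults define the package's standard validation conditions: 1,000
#' candidate loci, 12 demes on a line sampled by 3 datasets in contiguous
#' blocks, 40 diploids per location, 20% ambiguous (A/T, C/G) loci with half
#' of them strand-flipped in the non-reference datasets, 3 geographic
#' replicate locales, per-step divergence F = 0.02, and 2% missing calls per
#' dataset. Flips are injected only at ambiguous loci whose true minor
#' allele frequency at every replicate locale is at most
#' `flip_maf_ceiling` (default 0.35), the regime in which frequency-based
#' strand resolution is reliable; a flip at MAF near 0.5 is unidentifiable
#' in principle.
#'
#' @param seed integer RNG seed; a single global stream drives every
#'   stochastic step in documented order, so equal seeds give byte-identical
#'   output.
#' @param n_loci candidate loci in the shared core (before ascertainment).
#' @param n_populations demes on the stepping-stone line.
#' @param n_datasets number of datasets (>= 2); demes are split into
#'   contiguous blocks, dataset 1 (the reference) holding the first block.
#' @param per_pop_n diploid individuals per sampling location.
#' @param fst_divergence divergence parameter F in (0, 1): per-step variance
#'   of the stepping-stone frequency walk, or the Balding-Nichols F under
#'   `structure = "island"`.
#' @param ancestral_maf_range interval within (0, 0.5] for ancestral minor
#'   allele frequencies (drawn uniformly).
#' @param frac_ambiguous fraction of loci given A/T or C/G allele pairs.
#' @param frac_flipped fraction of ambiguous loci strand-flipped in each
#'   non-reference dataset (one shared flip set; capped by the number of
#'   flip-eligible loci).
#' @param flip_maf_ceiling flips are only injected where the true MAF at
#'   every replicate locale is at or below this value.
#' @param missing_rate per-dataset missing-call probability; scalar or
#'   length `n_datasets`.
#' @param replicate_locales number of demes in dataset 2's block that are
#'   also sampled (independently) by the reference dataset.
#' @param step_km distance between adjacent demes.
#' @param ascertainment_floor minimum MAF in the discovery deme for a locus
#'   to enter the panel (0 disables ascertainment).
#' @param discovery_population index of the discovery deme.
#' @param inbreeding_f within-population inbreeding coefficient (reduces
#'   heterozygote probability; 0 = Hardy-Weinberg proportions).
#' @param n_private_loci extra loci private to each dataset.
#' @param structure `"stepping_stone"` (default) or `"island"`
#'   (independent Balding-Nichols draws per deme).
#' @param replicate_identical draw the replicate locale in the alternate
#'   dataset as an exact copy of the reference sample instead of an
#'   independent draw (used for idealized no-noise checks).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 1000L,
                       n_populations = 12L,
                       n_datasets = 3L,
                       per_pop_n = 40L,
                       fst_divergence = 0.02,
                       ancestral_maf_range = c(0.05, 0.5),
                       frac_ambiguous = 0.2,
                       frac_flipped = 0.5,
                       flip_maf_ceiling = 0.35,
                       missing_rate = 0.02,
                       replicate_locales = 3L,
                       step_km = 150,
                       ascertainment_floor = 0,
                       discovery_population = 1L,
                       inbreeding_f = 0,
                       n_private_loci = 20L,
                       structure = c("stepping_stone", "island"),
                       replicate_identical = FALSE) {
  structure_model <- match.arg(structure)
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              n_populations = as.integer(n_populations),
              n_datasets = as.integer(n_datasets),
              per_pop_n = as.integer(per_pop_n),
              fst_divergence = fst_divergence,
              ancestral_maf_range = ancestral_maf_range,
              frac_ambiguous = frac_ambiguous,
              frac_flipped = frac_flipped,
              flip_maf_ceiling = flip_maf_ceiling,
              missing_rate = rep_len(missing_rate, n_datasets),
              replicate_locales = as.integer(replicate_locales),
              step_km = step_km,
              ascertainment_floor = ascertainment_floor,
              discovery_population = as.integer(discovery_population),
              inbreeding_f = inbreeding_f,
              n_private_loci = as.integer(n_private_loci),
              structure = structure_model,
              replicate_identical = isTRUE(replicate_identical))
  fr <- c(cfg$frac_ambiguous, cfg$frac_flipped, cfg$missing_rate,
          cfg$inbreeding_f)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$fst_divergence <= 0 || cfg$fst_divergence >= 1)
    stop("fst_divergence must lie in (0, 1)")
  if (cfg$n_datasets < 2) stop("n_datasets must be >= 2")
  if (cfg$replicate_locales < 1) stop("replicate_locales must be >= 1")
  if (cfg$n_populations < cfg$n_datasets)
    stop("need at least one deme per dataset")
  if (cfg$replicate_locales > cfg$n_populations)
    stop("replicate_locales exceeds n_populations")
  if (cfg$ascertainment_floor < 0 || cfg$ascertainment_floor > 0.5)
    stop("ascertainment_floor must lie in [0, 0.5]")
  if (min(cfg$ancestral_maf_range) <= 0 || max(cfg$ancestral_maf_range) > 0.5)
    stop("ancestral_maf_range must lie within (0, 0.5]")
  class(cfg) <- "sim_config"
  cfg
}

#' Balding-Nichols population allele frequencies
#'
#' Draws one frequency per population from the Balding-Nichols Beta
#' distribution with mean `ancestral_p` and variance
#' `F * ancestral_p * (1 - ancestral_p)`, i.e.
#' Beta(p(1-F)/F, (1-p)(1-F)/F): the standard divergence model
#' parameterized directly by FST.
#'
#' @param ancestral_p ancestral frequency in (0, 1).
#' @param F divergence parameter in (0, 1).
#' @param n_populations number of draws.
#' @return numeric vector of population frequencies.
#' @export
draw_population_frequencies <- function(ancestral_p, F, n_populations) {
  if (ancestral_p <= 0 || ancestral_p >= 1)
    stop("ancestral_p must lie in (0, 1)")
  if (F <= 0 || F >= 1) stop("F must lie in (0, 1)")
  stats::rbeta(n_populations, ancestral_p * (1 - F) / F,
               (1 - ancestral_p) * (1 - F) / F)
}

#' Stepping-stone population frequencies and distances
#'
#' Places `n_populations` demes on a line at `step_km` spacing. Each locus
#' starts from an ancestral frequency drawn uniformly from
#' `ancestral_maf_range` (randomly oriented to either allele) and evolves
#' deme-to-deme as a bounded random walk: each step draws from the
#' Balding-Nichols Beta around the previous deme's frequency with variance
#' `F p (1 - p)`, clipped to `[0.001, 0.999]` to avoid fixation
#' degeneracies. Divergence therefore accumulates with separation, producing
#' isolation by distance by construction.
#'
#' @param config a `sim_config`.
#' @return list with `freqs` (demes x loci matrix), `ancestral` (vector),
#'   `distances` (deme-level matrix, km).
#' @export
build_stepping_stone <- function(config) {
  if (config$n_populations < 3)
    stop("build_stepping_stone needs n_populations >= 3")
  L <- config$n_loci
  P <- config$n_populations
  maf <- stats::runif(L, config$ancestral_maf_range[1],
                      config$ancestral_maf_range[2])
  flip_orient <- stats::runif(L) < 0.5
  anc <- ifelse(flip_orient, 1 - maf, maf)
  freqs <- matrix(NA_real_, P, L)
  freqs[1, ] <- anc
  Fstep <- config$fst_divergence
  for (k in seq_len(P - 1)) {
    prev <- freqs[k, ]
    nxt <- stats::rbeta(L, prev * (1 - Fstep) / Fstep,
                        (1 - prev) * (1 - Fstep) / Fstep)
    freqs[k + 1, ] <- pmin(pmax(nxt, 0.001), 0.999)
  }
  demes <- sprintf("P%02d", seq_len(P))
  rownames(freqs) <- demes
  colnames(freqs) <- sprintf("snp%05d", seq_len(L))
  d <- abs(outer(seq_len(P), seq_len(P), "-")) * config$step_km
  dimnames(d) <- list(demes, demes)
  list(freqs = freqs, ancestral = stats::setNames(anc, colnames(freqs)),
       distances = d)
}

#' Ascertainment filter on a discovery population
#'
#' Keeps loci whose minor allele frequency in the discovery population is at
#' least `floor`, emulating a SNP panel discovered in (and therefore biased
#' toward diversity near) one end of the range.
#'
#' @param frequencies populations x loci frequency matrix.
#' @param discovery_pop row index of the discovery population.
#' @param floor minimum discovery-population MAF in `[0, 0.5]`.
#' @return integer vector of retained locus indices (error if empty).
#' @export
ascertain_loci <- function(frequencies, discovery_pop, floor) {
  if (floor < 0 || floor > 0.5) stop("floor must lie in [0, 0.5]")
  p <- frequencies[discovery_pop, ]
  keep <- which(pmin(p, 1 - p) >= floor)
  if (length(keep) == 0)
    stop("ascertainment retained no loci (floor = ", floor, ")")
  keep
}

# Parametric pairwise multi-locus FST between two demes from true
# frequencies: the large-sample limit of the Weir-Cockerham ratio-of-sums
# estimator under within-deme Hardy-Weinberg proportions,
#   sum_l (p1 - p2)^2 / 2  over  sum_l (pbar (1 - pbar) + (p1 - p2)^2 / 4).
truth_fst_pair <- function(p1, p2) {
  num <- (p1 - p2)^2 / 2
  pbar <- (p1 + p2) / 2
  den <- pbar * (1 - pbar) + (p1 - p2)^2 / 4
  sum(num) / sum(den)
}

#' Parametric pairwise FST matrix from true deme frequencies
#'
#' @param freqs demes x loci matrix of true allele frequencies.
#' @return symmetric matrix of parametric multi-locus FST.
#' @export
truth_pairwise_fst <- function(freqs) {
  P <- nrow(freqs)
  out <- matrix(0, P, P, dimnames = dimnames(freqs)[c(1, 1)])
  dimnames(out) <- list(rownames(freqs), rownames(freqs))
  for (i in seq_len(P - 1)) for (j in seq((i + 1), P)) {
    out[i, j] <- out[j, i] <- truth_fst_pair(freqs[i, ], freqs[j, ])
  }
  out
}

# Draw a dosage matrix for one sampling location: n diploids at the given
# per-locus frequencies, HWE within the location unless inbreeding_f > 0.
draw_location_dosages <- function(freqs, n, inbreeding_f = 0) {
  L <- length(freqs)
  if (inbreeding_f == 0) {
    m <- matrix(stats::rbinom(n * L, 2, rep(freqs, each = n)), nrow = n)
  } else {
    f <- inbreeding_f
    pAA <- freqs^2 + f * freqs * (1 - freqs)
    pAa <- 2 * freqs * (1 - freqs) * (1 - f)
    u <- matrix(stats::runif(n * L), nrow = n)
    m <- matrix(0L, n, L)
    m[u < rep(pAA + pAa, each = n)] <- 1L
    m[u < rep(pAA, each = n)] <- 2L
  }
  storage.mode(m) <- "integer"
  m
}

#' Draw a genotype panel from known population frequencies
#'
#' Samples `n_per_pop` diploids per deme with genotypes binomial at the true
#' frequency (Hardy-Weinberg within demes), used both internally by
#' [emit_datasets()] and directly in truth-recovery checks.
#'
#' @param freqs demes x loci matrix of designated-allele frequencies.
#' @param n_per_pop individuals per deme (scalar or per-deme vector).
#' @param loci optional locus table (defaults to unambiguous pairs A/C).
#' @param dataset dataset label.
#' @param inbreeding_f within-deme inbreeding coefficient.
#' @return a `genotype_panel` with one location per deme.
#' @export
draw_genotype_panel <- function(freqs, n_per_pop, loci = NULL,
                                dataset = "sim", inbreeding_f = 0) {
  P <- nrow(freqs)
  n_per_pop <- rep_len(n_per_pop, P)
  if (is.null(loci))
    loci <- data.frame(locus_id = colnames(freqs), allele1 = "A",
                       allele2 = "C", linkage_group = NA_character_,
                       stringsAsFactors = FALSE)
  dos <- do.call(rbind, lapply(seq_len(P), function(k)
    draw_location_dosages(freqs[k, ], n_per_pop[k], inbreeding_f)))
  codes <- rownames(freqs)
  individuals <- data.frame(
    individual_id = paste0(rep(codes, n_per_pop), "_",
                           unlist(lapply(n_per_pop, seq_len))),
    location_code = rep(codes, n_per_pop), stringsAsFactors = FALSE)
  genotype_panel(dos, loci, individuals, dataset = dataset)
}

#' Emit synthetic datasets with a truth ledger
#'
#' Runs the full generative model under a `sim_config`: stepping-stone (or
#' island) frequencies, ascertainment, allele-pair assignment, contiguous
#' deme blocks per dataset with geographic replicate locales between the
#' reference dataset and dataset 2, private loci, strand-flip injection at
#' ambiguous loci of every non-reference dataset, and per-dataset
#' missingness. All stochastic steps draw from one stream seeded with
#' `config$seed`, so equal configs give byte-identical output.
#'
#' @param config a `sim_config`.
#' @return list with `panels` (one `genotype_panel` per dataset), `pairs`
#'   (replicate-pair table: `locale`, `location_ref`, `dataset_ref`,
#'   `location_alt`, `dataset_alt`), and `truth` (a `truth_ledger`: ancestral
#'   and per-deme frequencies, flip set, parametric pairwise FST, deme- and
#'   location-level distance matrices, locus and location tables).
#' @export
emit_datasets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  P <- config$n_populations
  D <- config$n_datasets
  ds_names <- paste0("DS", LETTERS[seq_len(D)])

  # -- deme frequencies + distances --------------------------------------
  if (config$structure == "stepping_stone") {
    ss <- build_stepping_stone(config)
  } else {
    L <- config$n_loci
    maf <- stats::runif(L, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])
    orient <- stats::runif(L) < 0.5
    anc <- ifelse(orient, 1 - maf, maf)
    freqs <- t(vapply(seq_len(L), function(l)
      draw_population_frequencies(anc[l], config$fst_divergence, P),
      numeric(P)))
    freqs <- t(freqs)
    freqs <- pmin(pmax(freqs, 0.001), 0.999)
    rownames(freqs) <- sprintf("P%02d", seq_len(P))
    colnames(freqs) <- sprintf("snp%05d", seq_len(L))
    d <- abs(outer(seq_len(P), seq_len(P), "-")) * config$step_km
    dimnames(d) <- list(rownames(freqs), rownames(freqs))
    ss <- list(freqs = freqs, ancestral = stats::setNames(anc,
               colnames(freqs)), distances = d)
  }

  # -- ascertainment ------------------------------------------------------
  keep <- if (config$ascertainment_floor > 0) {
    ascertain_loci(ss$freqs, config$discovery_population,
                   config$ascertainment_floor)
  } else seq_len(ncol(ss$freqs))
  freqs <- ss$freqs[, keep, drop = FALSE]
  anc <- ss$ancestral[keep]
  core_ids <- colnames(freqs)
  Lc <- length(core_ids)

  # -- allele pairs -------------------------------------------------------
  n_amb <- round(config$frac_ambiguous * Lc)
  amb_idx <- sort(sample.int(Lc, n_amb))
  amb_pair <- sample(c("A/T", "C/G"), n_amb, replace = TRUE)
  unamb_pool <- c("A/C", "A/G", "C/T", "G/T")
  pair <- sample(unamb_pool, Lc, replace = TRUE)
  pair[amb_idx] <- amb_pair
  a1 <- substr(pair, 1, 1)
  a2 <- substr(pair, 3, 3)
  # randomize which allele of the pair is the designated (frequency-bearing)
  swap <- stats::runif(Lc) < 0.5
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  core_loci <- data.frame(locus_id = core_ids, allele1 = a1, allele2 = a2,
                          linkage_group = NA_character_,
                          stringsAsFactors = FALSE)

  # -- deme blocks, replicate locales ------------------------------------
  block <- sort(rep_len(seq_len(D), P))  # contiguous blocks west -> east
  deme_codes <- rownames(freqs)
  locales <- which(block == 2)[seq_len(min(config$replicate_locales,
                                           sum(block == 2)))]
  pairs <- data.frame(
    locale = deme_codes[locales],
    location_ref = paste0(deme_codes[locales], "r"),
    dataset_ref = ds_names[1],
    location_alt = deme_codes[locales],
    dataset_alt = ds_names[2],
    stringsAsFactors = FALSE)

  # -- flip set (shared across non-reference datasets) -------------------
  # eligibility is judged where resolution happens: the true MAF at every
  # replicate locale must not exceed the ceiling (higher-MAF flips are
  # unidentifiable by frequency comparison in principle)
  locale_maf <- apply(pmin(freqs[locales, , drop = FALSE],
                           1 - freqs[locales, , drop = FALSE]), 2, max)
  eligible <- intersect(amb_idx,
                        which(locale_maf <= config$flip_maf_ceiling))
  n_flip <- min(round(config$frac_flipped * n_amb), length(eligible))
  flip_idx <- sort(sample(eligible, n_flip))
  flip_ids <- core_ids[flip_idx]
  flips <- if (D > 1 && n_flip > 0) {
    data.frame(locus_id = rep(flip_ids, D - 1),
               dataset = rep(ds_names[-1], each = n_flip),
               stringsAsFactors = FALSE)
  } else data.frame(locus_id = character(0), dataset = character(0))

  # -- per-dataset panels -------------------------------------------------
  panels <- vector("list", D)
  names(panels) <- ds_names
  location_rows <- list()
  for (d in seq_len(D)) {
    demes_d <- which(block == d)
    # private loci for this dataset
    if (config$n_private_loci > 0) {
      Lp <- config$n_private_loci
      maf_p <- stats::runif(Lp, config$ancestral_maf_range[1],
                            config$ancestral_maf_range[2])
      priv_f <- matrix(rep(maf_p, each = P), P)  # flat across demes
      colnames(priv_f) <- sprintf("prv%s%04d", LETTERS[d], seq_len(Lp))
      rownames(priv_f) <- deme_codes
      priv_pair <- sample(unamb_pool, Lp, replace = TRUE)
      priv_loci <- data.frame(locus_id = colnames(priv_f),
                              allele1 = substr(priv_pair, 1, 1),
                              allele2 = substr(priv_pair, 3, 3),
                              linkage_group = NA_character_,
                              stringsAsFactors = FALSE)
      f_all <- cbind(freqs, priv_f)
      loci_all <- rbind(core_loci, priv_loci)
    } else {
      f_all <- freqs
      loci_all <- core_loci
    }
    own <- draw_genotype_panel(f_all[demes_d, , drop = FALSE],
                               config$per_pop_n, loci_all,
                               dataset = ds_names[d],
                               inbreeding_f = config$inbreeding_f)
    # reference dataset additionally samples the replicate locales
    if (d == 1 && length(locales) > 0) {
      f_rep <- f_all[locales, , drop = FALSE]
      rownames(f_rep) <- paste0(deme_codes[locales], "r")
      rep_panel <- draw_genotype_panel(f_rep, config$per_pop_n, loci_all,
                                       dataset = ds_names[1],
                                       inbreeding_f = config$inbreeding_f)
      own <- merge_panels(list(own, rep_panel), loci_all$locus_id)
      own$samples$dataset <- ds_names[1]
    }
    panels[[d]] <- own
    location_rows[[d]] <- data.frame(
      location_code = own$samples$location_code,
      dataset = ds_names[d],
      deme = sub("r$", "", own$samples$location_code),
      stringsAsFactors = FALSE)
  }

  # idealized replicates: copy reference dosages into the alternate sample
  if (config$replicate_identical && length(locales) > 0) {
    p1 <- panels[[1]]; p2 <- panels[[2]]
    for (k in seq_len(nrow(pairs))) {
      src <- p1$dosages[p1$individuals$location_code == pairs$location_ref[k],
                        core_ids, drop = FALSE]
      dst <- which(p2$individuals$location_code == pairs$location_alt[k])
      p2$dosages[dst, core_ids] <- src[seq_along(dst), ]
    }
    panels[[2]] <- p2
  }

  # -- strand-flip injection ---------------------------------------------
  if (nrow(flips) > 0) {
    for (d in ds_names[-1]) {
      ids <- flips$locus_id[flips$dataset == d]
      panels[[d]] <- apply_strand_flip(panels[[d]], ids)
    }
  }

  # -- missingness --------------------------------------------------------
  for (d in seq_len(D)) {
    rate <- config$missing_rate[d]
    if (rate > 0) {
      dm <- panels[[d]]$dosages
      mask <- matrix(stats::runif(length(dm)) < rate, nrow(dm))
      dm[mask] <- NA_integer_
      panels[[d]]$dosages <- dm
    }
  }

  locations <- do.call(rbind, location_rows)
  loc_dist <- ss$distances[locations$deme, locations$deme]
  dimnames(loc_dist) <- list(locations$location_code,
                             locations$location_code)
  truth <- structure(list(
    ancestral = anc,
    freqs = freqs,
    flips = flips,
    parametric_fst = truth_pairwise_fst(freqs),
    deme_distances = ss$distances,
    location_distances = loc_dist,
    loci = core_loci,
    locations = locations,
    config = config
  ), class = "truth_ledger")
  list(panels = panels, pairs = pairs, truth = truth)
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat("<truth_ledger> ", ncol(x$freqs), " core loci, ", nrow(x$freqs),
      " demes, ", nrow(x$flips), " injected (locus, dataset) flips\n",
      sep = "")
  invisible(x)
}

#' Write truth-ledger tables as TSV
#'
#' @param truth a `truth_ledger`.
#' @param prefix file prefix; writes `<prefix>.freqs.tsv`,
#'   `<prefix>.flips.tsv`, `<prefix>.parametric_fst.tsv`,
#'   `<prefix>.loci.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_truth_ledger <- function(truth, prefix) {
  write_tsv(data.frame(deme = rownames(truth$freqs), truth$freqs,
                       check.names = FALSE), paste0(prefix, ".freqs.tsv"))
  write_tsv(truth$flips, paste0(prefix, ".flips.tsv"))
  write_tsv(data.frame(deme = rownames(truth$parametric_fst),
                       truth$parametric_fst, check.names = FALSE),
            paste0(prefix, ".parametric_fst.tsv"))
  write_tsv(truth$loci, paste0(prefix, ".loci.tsv"))
  invisible(prefix)
}
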