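#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
AMBIGUOUS_PAIRS <- c("A/T", "C/G")

#' Construct a genotype panel
#'
#' The central container of the package: a set of biallelic loci, a set of
#' sampling locations, and a diploid dosage matrix. Dosages count copies of
#' the *designated* allele of each locus, which is always `allele1` of the
#' locus table; missing genotypes are `NA`. Keeping the designation explicit
#' makes strand handling auditable: complementary relabelling of a locus maps
#' dosage g to 2 - g, and all read/write paths preserve the designation so
#' this never happens silently.
#'
#' @param dosages integer matrix, individuals x loci, entries in
#'   `c(0L, 1L, 2L, NA)`. Row names are individual ids, column names locus ids
#'   (supplied via `individuals` / `loci` if absent).
#' @param loci data frame with columns `locus_id`, `allele1`, `allele2`
#'   (single bases from A/C/G/T; `allele2` may be `NA` when unrecoverable from
#'   a file), and optionally `linkage_group`.
#' @param individuals data frame with columns `individual_id`,
#'   `location_code`.
#' @param samples optional data frame with columns `location_code`, `dataset`,
#'   `n_individuals`, `lat`, `lon`; derived from `individuals` when `NULL`.
#' @param dataset dataset-of-origin label used when deriving `samples`.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, loci, individuals, samples = NULL,
                           dataset = "panel") {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (!"linkage_group" %in% names(loci)) loci$linkage_group <- NA_character_
  rownames(dosages) <- individuals$individual_id
  colnames(dosages) <- loci$locus_id
  if (is.null(samples)) {
    locs <- unique(individuals$location_code)
    samples <- data.frame(
      location_code = locs,
      dataset = dataset,
      n_individuals = as.integer(table(individuals$location_code)[locs]),
      lat = NA_real_, lon = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  panel <- structure(
    list(dosages = dosages, loci = loci, individuals = individuals,
         samples = samples),
    class = "genotype_panel"
  )
  validate_panel(panel)
  panel
}

#' Validate genotype panel invariants
#'
#' Checks matrix dimensions, dosage range, allele validity and distinctness,
#' uniqueness of locus ids and location codes, and that every individual's
#' location exists in the sample table. Stops with an informative message on
#' the first violation.
#'
#' @param panel a `genotype_panel`.
#' @return the panel, invisibly.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  if (nrow(d) != nrow(panel$individuals))
    stop("dosage rows (", nrow(d), ") != individuals (",
         nrow(panel$individuals), ")")
  if (ncol(d) != nrow(panel$loci))
    stop("dosage columns (", ncol(d), ") != loci (", nrow(panel$loci), ")")
  bad <- !(d %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(panel$loci$locus_id))
    stop("duplicated locus_id in panel")
  if (!all(panel$loci$allele1 %in% BASES))
    stop("allele1 outside A/C/G/T")
  a2 <- panel$loci$allele2
  if (!all(is.na(a2) | a2 %in% BASES))
    stop("allele2 outside A/C/G/T")
  same <- !is.na(a2) & a2 == panel$loci$allele1
  if (any(same))
    stop("allele pair not distinct at locus ",
         panel$loci$locus_id[which(same)[1]])
  if (anyDuplicated(panel$samples[, c("location_code", "dataset")]))
    stop("duplicated (location_code, dataset) in samples")
  if (anyDuplicated(panel$samples$location_code))
    stop("location codes must be unique within a panel")
  if (any(panel$samples$n_individuals < 1))
    stop("samples must have n_individuals >= 1")
  orphan <- !panel$individuals$location_code %in% panel$samples$location_code
  if (any(orphan))
    stop("individual ", panel$individuals$individual_id[which(orphan)[1]],
         " has a location_code absent from the sample table")
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$individuals), " individuals, ",
      nrow(x$loci), " loci, ", nrow(x$samples), " sampling locations (",
      paste(unique(x$samples$dataset), collapse = ", "), ")\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat("  missing genotypes: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Test whether loci are strand-ambiguous
#'
#' A biallelic SNP is strand-ambiguous when its unordered allele pair is
#' A/T or C/G: the pair equals its own reverse complement, so the sequenced
#' strand cannot be recovered from allele identities alone and must be
#' resolved by allele-frequency comparison.
#'
#' @param allele1,allele2 character vectors of single bases. `allele1` may
#'   instead be a locus table (a data frame with `allele1`/`allele2` columns),
#'   in which case `allele2` is ignored.
#' @return logical vector; `NA` alleles give `FALSE`.
#' @export
is_ambiguous <- function(allele1, allele2 = NULL) {
  if (is.data.frame(allele1)) {
    allele2 <- allele1$allele2
    allele1 <- allele1$allele1
  }
  key <- paste(pmin(allele1, allele2), pmax(allele1, allele2), sep = "/")
  !is.na(allele2) & !is.na(allele1) & key %in% AMBIGUOUS_PAIRS
}

#' Allele frequency of the designated allele at one locus and location
#'
#' Frequency of the panel's designated allele (`allele1`) among non-missing
#' calls, `sum(dosage) / (2 * n_called)`. A location with zero calls yields
#' frequency `NA` (propagated downstream as inconclusive, never an error).
#'
#' @param panel a `genotype_panel`.
#' @param location_code a location present in the panel.
#' @param locus_id a locus present in the panel.
#' @return list with elements `freq` and `n_called`.
#' @export
allele_frequency <- function(panel, location_code, locus_id) {
  if (!location_code %in% panel$samples$location_code)
    stop("unknown location_code: ", location_code)
  if (!locus_id %in% panel$loci$locus_id)
    stop("unknown locus_id: ", locus_id)
  g <- panel$dosages[panel$individuals$location_code == location_code,
                     locus_id]
  n_called <- sum(!is.na(g))
  freq <- if (n_called == 0) NA_real_ else sum(g, na.rm = TRUE) / (2 * n_called)
  list(freq = freq, n_called = n_called)
}

# Designated-allele frequencies for every locus at one location.
# Returns list(freq, n_called), each a vector over panel loci.
location_freqs <- function(panel, location_code, locus_ids = NULL) {
  g <- panel$dosages[panel$individuals$location_code == location_code, ,
                     drop = FALSE]
  if (!is.null(locus_ids)) g <- g[, locus_ids, drop = FALSE]
  n_called <- colSums(!is.na(g))
  freq <- ifelse(n_called == 0, NA_real_,
                 colSums(g, na.rm = TRUE) / (2 * n_called))
  list(freq = freq, n_called = n_called)
}

# Per-location genotype counts for every locus: list of matrices
# (n2 = hom designated, n1 = het, n0 = hom other), each locations x loci.
genotype_counts <- function(panel, locus_ids = NULL) {
  d <- panel$dosages
  if (!is.null(locus_ids)) d <- d[, locus_ids, drop = FALSE]
  loc <- panel$individuals$location_code
  locs <- panel$samples$location_code
  count_of <- function(v) {
    m <- rowsum((!is.na(d) & d == v) + 0L, loc)
    m[match(locs, rownames(m)), , drop = FALSE]
  }
  n2 <- count_of(2L); n1 <- count_of(1L); n0 <- count_of(0L)
  rownames(n2) <- rownames(n1) <- rownames(n0) <- locs
  list(n2 = n2, n1 = n1, n0 = n0)
}

#' Flip the strand reading of ambiguous loci
#'
#' Re-expresses the named ambiguous loci on the complementary strand: the
#' allele pair, being its own reverse complement, is unchanged, and the
#' dosage of the designated allele maps g to 2 - g. Applying the same flip
#' twice restores the panel exactly (involution).
#'
#' @param panel a `genotype_panel`.
#' @param locus_ids loci to flip; all must be strand-ambiguous.
#' @return the modified panel.
#' @export
apply_strand_flip <- function(panel, locus_ids) {
  if (length(locus_ids) == 0) return(panel)
  idx <- match(locus_ids, panel$loci$locus_id)
  if (anyNA(idx)) stop("unknown locus_id in flip set")
  amb <- is_ambiguous(panel$loci[idx, ])
  if (!all(amb))
    stop("apply_strand_flip is defined for ambiguous (A/T, C/G) loci only")
  panel$dosages[, idx] <- 2L - panel$dosages[, idx]
  panel
}

# Swap the designated allele of arbitrary loci: allele1 <-> allele2 and
# dosage g -> 2 - g. Used to align designations across panels.
swap_designation <- function(panel, locus_ids) {
  if (length(locus_ids) == 0) return(panel)
  idx <- match(locus_ids, panel$loci$locus_id)
  a1 <- panel$loci$allele1[idx]
  panel$loci$allele1[idx] <- panel$loci$allele2[idx]
  panel$loci$allele2[idx] <- a1
  panel$dosages[, idx] <- 2L - panel$dosages[, idx]
  panel
}

#' Canonicalize allele designation
#'
#' Re-designates every locus so that `allele1` is the alphabetically first
#' allele of the pair (the convention a Genepop file imposes, where the lower
#' allele code is designated). Useful for comparing panels that went through
#' different serialization paths.
#'
#' @param panel a `genotype_panel`.
#' @return the re-designated panel.
#' @export
canonicalize_designation <- function(panel) {
  swap <- !is.na(panel$loci$allele2) & panel$loci$allele1 > panel$loci$allele2
  swap_designation(panel, panel$loci$locus_id[swap])
}

#' Subset a panel by loci and/or individuals
#'
#' @param panel a `genotype_panel`.
#' @param locus_ids loci to keep (default all), in the given order.
#' @param location_codes locations to keep (default all).
#' @return the subset `genotype_panel`.
#' @export
subset_panel <- function(panel, locus_ids = NULL, location_codes = NULL) {
  if (!is.null(locus_ids)) {
    idx <- match(locus_ids, panel$loci$locus_id)
    if (anyNA(idx)) stop("unknown locus_id in subset")
    panel$loci <- panel$loci[idx, , drop = FALSE]
    panel$dosages <- panel$dosages[, idx, drop = FALSE]
    rownames(panel$loci) <- NULL
  }
  if (!is.null(location_codes)) {
    keep_s <- panel$samples$location_code %in% location_codes
    keep_i <- panel$individuals$location_code %in% location_codes
    panel$samples <- panel$samples[keep_s, , drop = FALSE]
    panel$individuals <- panel$individuals[keep_i, , drop = FALSE]
    panel$dosages <- panel$dosages[keep_i, , drop = FALSE]
    rownames(panel$samples) <- rownames(panel$individuals) <- NULL
  }
  validate_panel(panel)
  panel
}

#' Concatenate panels over a common locus set
#'
#' Stacks the individuals of several panels over loci shared by all of them
#' (allele designations must already be aligned, as done by
#' [intersect_panels()]). Location codes must be unique across panels; the
#' merged sample table keeps each location's dataset of origin as provenance.
#'
#' @param panels list of `genotype_panel` objects.
#' @param locus_ids loci to retain, present in every panel.
#' @return the merged `genotype_panel`.
#' @export
merge_panels <- function(panels, locus_ids) {
  stopifnot(length(panels) >= 1)
  ref <- subset_panel(panels[[1]], locus_ids)
  loci <- ref$loci
  dosages <- do.call(rbind, lapply(panels, function(p)
    subset_panel(p, locus_ids)$dosages))
  individuals <- do.call(rbind, lapply(panels, `[[`, "individuals"))
  samples <- do.call(rbind, lapply(panels, `[[`, "samples"))
  rownames(individuals) <- rownames(samples) <- NULL
  genotype_panel(dosages, loci, individuals, samples)
}
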