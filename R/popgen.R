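# Population-genetic statistics. The Weir & Cockerham (1984) variance
# components, the Hardy-Weinberg exact test and the Mantel permutation test
# are implemented natively; negative theta estimates are reported as-is
# (no clamping), which the identical-replicate-sample diagnostics rely on.

#' Observed and expected heterozygosity at one location
#'
#' Per locus: Ho = fraction of heterozygotes among called individuals;
#' He = 1 - p^2 - q^2 = 2pq for a biallelic locus; uHe = He * 2n/(2n - 1)
#' (the small-sample unbiased estimate). Location means are unweighted means
#' over loci with at least one call; loci with zero calls are excluded from
#' the means and counted in the summary.
#'
#' @param panel a `genotype_panel`.
#' @param location_code location to summarize.
#' @return a `het_summary`: list with `per_locus` data frame
#'   (`locus_id`, `n_called`, `Ho`, `He`, `uHe`) and `means`
#'   (`Ho`, `He`, `uHe`, `n_loci_used`, `n_loci_uncalled`).
#' @export
heterozygosity <- function(panel, location_code) {
  if (!location_code %in% panel$samples$location_code)
    stop("unknown location_code: ", location_code)
  g <- panel$dosages[panel$individuals$location_code == location_code, ,
                     drop = FALSE]
  n <- colSums(!is.na(g))
  nhet <- colSums(g == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  Ho <- ifelse(n > 0, nhet / n, NA_real_)
  He <- 2 * p * (1 - p)
  uHe <- ifelse(n > 0, He * (2 * n) / (2 * n - 1), NA_real_)
  used <- n > 0
  per_locus <- data.frame(locus_id = panel$loci$locus_id, n_called = n,
                          Ho = Ho, He = He, uHe = uHe,
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    location_code = location_code,
    per_locus = per_locus,
    means = c(Ho = mean(Ho[used]), He = mean(He[used]),
              uHe = mean(uHe[used]),
              n_loci_used = sum(used), n_loci_uncalled = sum(!used))
  ), class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat("<het_summary> ", x$location_code, ": mean Ho = ",
      sprintf("%.4f", x$means[["Ho"]]), ", mean He = ",
      sprintf("%.4f", x$means[["He"]]), " over ",
      x$means[["n_loci_used"]], " loci\n", sep = "")
  invisible(x)
}

# Vectorized Weir & Cockerham (1984) variance components for r populations.
# Inputs are populations x loci matrices of sample size (called individuals),
# designated-allele frequency, and observed heterozygote fraction. Loci where
# fewer than 2 populations have calls, or where nbar <= 1, yield NA
# components. Returns list(a, b, c) of per-locus vectors.
wc_components <- function(nmat, pmat, hmat) {
  present <- !is.na(pmat) & nmat > 0
  r <- colSums(present)
  nmat0 <- ifelse(present, nmat, 0)
  pmat0 <- ifelse(present, pmat, 0)
  hmat0 <- ifelse(present, hmat, 0)
  nsum <- colSums(nmat0)
  nbar <- nsum / r
  nc <- (nsum - colSums(nmat0^2) / nsum) / (r - 1)
  pbar <- colSums(nmat0 * pmat0) / nsum
  s2 <- colSums(nmat0 * sweep(pmat0, 2, pbar)^2 * present) / ((r - 1) * nbar)
  hbar <- colSums(nmat0 * hmat0) / nsum
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham variance components and theta at a single locus
#'
#' The Weir & Cockerham (1984) unbiased estimator for unequal sample sizes:
#' variance components a (among populations), b (among individuals within
#' populations) and c (within individuals), with
#' theta = a / (a + b + c). Theta may be negative (identical samples give a
#' non-positive estimate) and is `NA` (undefined) when a + b + c = 0, i.e.
#' when all populations are monomorphic for the same allele.
#'
#' @param counts matrix (or coercible) with one row per population and three
#'   columns: number of individuals homozygous for the designated allele,
#'   heterozygous, and homozygous for the other allele.
#' @return list with `a`, `b`, `c`, `theta`.
#' @export
wc_theta_per_locus <- function(counts) {
  counts <- matrix(as.numeric(counts), ncol = 3)
  if (nrow(counts) < 2)
    stop("wc_theta_per_locus needs at least 2 populations")
  n <- rowSums(counts)
  if (any(n < 1)) stop("each population needs at least 1 called individual")
  p <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
  h <- counts[, 2] / n
  comp <- wc_components(cbind(n), cbind(p), cbind(h))
  a <- unname(comp$a[[1]]); b <- unname(comp$b[[1]])
  cc <- unname(comp$c[[1]])
  denom <- a + b + cc
  theta <- if (is.na(denom) || denom == 0) NA_real_ else a / denom
  list(a = a, b = b, c = cc, theta = theta)
}

# Per-locus WC components between two locations of a panel, vectorized over
# loci. cnt = genotype_counts(panel) (optionally precomputed).
pair_wc <- function(panel, loc_a, loc_b, cnt = NULL) {
  if (is.null(cnt)) cnt <- genotype_counts(panel)
  pick <- function(loc) {
    n2 <- cnt$n2[loc, ]; n1 <- cnt$n1[loc, ]; n0 <- cnt$n0[loc, ]
    n <- n2 + n1 + n0
    list(n = n,
         p = ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_),
         h = ifelse(n > 0, n1 / n, NA_real_))
  }
  A <- pick(loc_a); B <- pick(loc_b)
  comp <- wc_components(rbind(A$n, B$n), rbind(A$p, B$p), rbind(A$h, B$h))
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(is.na(denom) | denom == 0, NA_real_, comp$a / denom)
  data.frame(locus_id = colnames(cnt$n2), a = comp$a, b = comp$b, c = comp$c,
             denom = denom, theta = theta, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pairwise multi-locus FST between all sampling locations
#'
#' For every pair of locations, per-locus Weir-Cockerham variance components
#' and the multi-locus estimate as a ratio of sums,
#' theta = sum(a) / sum(a + b + c) over loci with a defined denominator
#' (never a mean of per-locus ratios). Pairs sharing no locus with a defined
#' denominator get `NA` with a warning.
#'
#' @param panel a `genotype_panel` with at least 2 locations.
#' @param per_locus keep the per-locus component tables (memory-heavier).
#' @return a `pairwise_fst` object: list with `theta` (symmetric matrix,
#'   zero diagonal by convention) and, if requested, `pairs` (named list of
#'   per-locus data frames).
#' @export
pairwise_fst <- function(panel, per_locus = FALSE) {
  locs <- panel$samples$location_code
  if (length(locs) < 2) stop("pairwise_fst needs at least 2 locations")
  cnt <- genotype_counts(panel)
  theta <- matrix(0, length(locs), length(locs),
                  dimnames = list(locs, locs))
  pairs <- list()
  for (i in seq_along(locs)[-length(locs)]) {
    for (j in seq((i + 1), length(locs))) {
      pl <- pair_wc(panel, locs[i], locs[j], cnt)
      ok <- !is.na(pl$denom) & pl$denom != 0
      if (!any(ok)) {
        warning("locations ", locs[i], " and ", locs[j],
                " share no locus with defined FST")
        th <- NA_real_
      } else {
        th <- sum(pl$a[ok]) / sum(pl$denom[ok])
      }
      theta[i, j] <- theta[j, i] <- th
      if (per_locus) pairs[[paste(locs[i], locs[j], sep = "~")]] <- pl
    }
  }
  structure(list(theta = theta, pairs = if (per_locus) pairs else NULL),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  v <- x$theta[upper.tri(x$theta)]
  cat("<pairwise_fst> ", nrow(x$theta), " locations; multi-locus theta ",
      "range [", sprintf("%.4f", min(v, na.rm = TRUE)), ", ",
      sprintf("%.4f", max(v, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test for a biallelic locus: given the allele counts, the
#' heterozygote count follows a known discrete distribution under
#' Hardy-Weinberg equilibrium; the p-value is the total probability of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (full enumeration). Monomorphic samples return p = 1
#' by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygote, heterozygote,
#'   homozygote).
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("hwe_exact_test needs at least 1 individual")
  nA <- 2 * n_AA + n_Aa
  na_ <- 2 * n_aa + n_Aa
  if (nA == 0 || na_ == 0) return(1)
  rare <- min(nA, na_)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | n, nA) up to a constant shared by all h
  lp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na_ - hets) / 2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Vectorized/memoized batch of HWE exact tests.
hwe_exact_batch <- function(n_AA, n_Aa, n_aa) {
  key <- paste(n_AA, n_Aa, n_aa)
  first <- !duplicated(key)
  pu <- vapply(which(first),
               function(i) hwe_exact_test(n_AA[i], n_Aa[i], n_aa[i]),
               numeric(1))
  pu[match(key, key[first])]
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH false-discovery-rate adjustment (pi0 = 1, hence conservative
#' relative to q-value estimators that fit pi0).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Welch two-sample t test
#'
#' Welch's unequal-variance statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value, as used to compare mean pairwise FST between
#' regional groups.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("welch_t needs n >= 2 in each group")
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      stop("welch_t undefined: zero variance in both groups and equal means")
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, df = NA_real_,
                p = 0))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Loci in the upper tail of per-locus FST
#'
#' Returns the loci whose theta is at or above the empirical `quantile`
#' (linear-interpolation definition, `stats::quantile` type 7); all ties at
#' the cut are included. Undefined (NA) theta values are excluded from the
#' quantile population.
#'
#' @param theta named numeric vector of per-locus theta (names = locus ids).
#' @param quantile the cut, default 0.95.
#' @return character vector of locus ids, sorted.
#' @export
upper_quantile_loci <- function(theta, quantile = 0.95) {
  ok <- !is.na(theta)
  if (!any(ok)) stop("all theta values undefined")
  cut <- stats::quantile(theta[ok], probs = quantile, type = 7, names = FALSE)
  sort(names(theta)[ok & theta >= cut])
}
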