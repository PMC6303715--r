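# Mantel test of isolation by distance on Rousset-linearized FST.

# All permutations of 1..n (n! x n matrix), recursive construction; intended
# for small n only (exhaustive Mantel reference on <= 8 labels).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[row:(row + nrow(sub) - 1), 1] <- k
    out[row:(row + nrow(sub) - 1), -1] <- matrix(rest[sub], nrow(sub))
    row <- row + nrow(sub)
  }
  out
}

#' Mantel test between an FST matrix and a distance matrix
#'
#' Pearson correlation between the upper-triangle entries of the two
#' matrices, with significance from joint row/column permutation of one
#' matrix. With `linearize = TRUE` (default) FST entries are transformed to
#' FST/(1 - FST) before correlating, the standard linearization for
#' isolation-by-distance regression. The test is one-tailed (greater) by
#' default because isolation by distance predicts a positive correlation.
#'
#' The permutation p-value uses the add-one rule,
#' p = (1 + #\{r* >= r_obs\}) / (1 + n_permutations), and so is never exactly
#' zero. When `n_permutations` covers the whole permutation group
#' (n_permutations >= n! - 1) the test enumerates all label permutations
#' instead of sampling, making the p-value exact and seed-free.
#'
#' @param fst_matrix symmetric matrix of pairwise FST with location labels.
#' @param distance_matrix symmetric distance matrix, same labels and order.
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed for the permutation draw (required when
#'   sampling; recorded in the result).
#' @param linearize transform FST to FST/(1 - FST) first (requires all
#'   FST < 1).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return a `mantel_result`: list with `r`, `p`, `n_permutations`,
#'   `exhaustive`, `seed`, `linearized`, `alternative`.
#' @export
mantel_ibd <- function(fst_matrix, distance_matrix, n_permutations = 9999,
                       seed = NULL, linearize = TRUE,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(fst_matrix)
  m2 <- as.matrix(distance_matrix)
  if (!identical(dim(m1), dim(m2)))
    stop("matrices differ in dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrix labels differ or are ordered differently")
  n <- nrow(m1)
  if (n < 3) stop("mantel_ibd needs at least 3 locations")
  if (linearize) {
    if (any(m1 >= 1, na.rm = TRUE))
      stop("cannot linearize: FST >= 1 present")
    m1 <- m1 / (1 - m1)
  }
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  v2 <- m2[ut]
  if (anyNA(v1) || anyNA(v2)) stop("NA entries in matrices")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("degenerate input: constant matrix, Mantel r undefined")
  r_obs <- stats::cor(v1, v2)
  tol <- 1e-12
  exhaustive <- factorial(n) - 1 <= n_permutations && n <= 8
  if (exhaustive) {
    perms <- all_permutations(n)[-1, , drop = FALSE]  # drop identity
  } else {
    if (is.null(seed)) stop("seed is required for sampled permutations")
    set.seed(seed)
    perms <- t(replicate(n_permutations, sample.int(n)))
  }
  r_perm <- apply(perms, 1, function(pm) stats::cor(m1[pm, pm][ut], v2))
  hits <- if (alternative == "greater") {
    sum(r_perm >= r_obs - tol)
  } else {
    sum(abs(r_perm) >= abs(r_obs) - tol)
  }
  structure(list(r = r_obs, p = (1 + hits) / (1 + nrow(perms)),
                 n_permutations = nrow(perms), exhaustive = exhaustive,
                 seed = if (exhaustive) NA_integer_ else seed,
                 linearized = linearize, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("<mantel_result> r = ", sprintf("%.4f", x$r), ", p = ",
      format(x$p, digits = 4), " (", x$n_permutations,
      if (x$exhaustive) " exhaustive" else " sampled", " permutations, ",
      x$alternative, if (x$linearized) ", FST/(1-FST)", ")\n", sep = "")
  invisible(x)
}

#' Welch comparison of within- vs between-region pairwise FST
#'
#' Splits the off-diagonal pairwise multi-locus FST values by whether the two
#' locations fall in the same region, then applies [welch_t()]. This mirrors
#' the regional-differentiation contrast of the range-wide analysis (pairs
#' spanning two regions versus pairs within a region).
#'
#' @param fst_matrix symmetric pairwise FST matrix with location labels.
#' @param regions named character vector mapping every location to a region.
#' @return list with `t`, `df`, `p`, `n_within`, `n_between` and the two
#'   value vectors.
#' @export
regional_fst_welch <- function(fst_matrix, regions) {
  labs <- rownames(fst_matrix)
  if (!all(labs %in% names(regions)))
    stop("regions must name every location in the FST matrix")
  reg <- regions[labs]
  ut <- which(upper.tri(fst_matrix), arr.ind = TRUE)
  same <- reg[ut[, 1]] == reg[ut[, 2]]
  vals <- fst_matrix[upper.tri(fst_matrix)]
  res <- welch_t(vals[same], vals[!same])
  c(res, list(n_within = sum(same), n_between = sum(!same),
              within = vals[same], between = vals[!same]))
}
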