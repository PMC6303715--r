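# Independent reference implementations used as oracles. These deliberately
# use different code paths (scalar loops, direct factorials, recursive
# permutation enumeration) from the package's vectorized implementations.

# Weir & Cockerham (1984) variance components, direct scalar transcription
# of the general-r formulas.
wc_oracle <- function(counts) {
  counts <- matrix(as.numeric(counts), ncol = 3)
  r <- nrow(counts)
  n <- rowSums(counts)
  p <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
  h <- counts[, 2] / n
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- if (a + b + cc == 0) NA_real_ else a / (a + b + cc)
  list(a = a, b = b, c = cc, theta = theta)
}

# HWE exact test by full enumeration with direct factorial arithmetic
# (valid for n <= ~80 before overflow).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na_ <- 2 * n - nA
  if (nA == 0 || na_ == 0) return(1)
  rare <- min(nA, na_)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    n1 <- (nA - h) / 2
    n2 <- (na_ - h) / 2
    factorial(n) / (factorial(n1) * factorial(h) * factorial(n2)) *
      2^h / choose(2 * n, nA)
  }, numeric(1))
  obs <- prob[hets == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

# All permutations of 1..n by simple recursion (oracle for the exhaustive
# Mantel reference).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (sub in perms_oracle(n - 1)) {
      rest <- seq_len(n)[-k]
      out[[length(out) + 1]] <- c(k, rest[sub])
    }
  }
  out
}

# Exhaustive Mantel p-value: proportion of ALL label permutations (identity
# included) whose correlation is >= the observed.
mantel_exhaustive_oracle <- function(m1, m2) {
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v2 <- m2[ut]
  r_obs <- cor(m1[ut], v2)
  rs <- vapply(perms_oracle(n),
               function(pm) cor(m1[pm, pm][ut], v2), numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Upper-quantile membership by explicit sort-and-scan.
top_set_oracle <- function(theta, q) {
  theta <- theta[!is.na(theta)]
  cut <- stats::quantile(theta, q, type = 7, names = FALSE)
  ord <- sort(names(theta))
  sort(ord[theta[ord] >= cut])
}

# Welch t by hand formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
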