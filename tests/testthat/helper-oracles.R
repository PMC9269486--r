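## Independent oracles used across the suite. These deliberately do not
## call the code paths they check.

## Brute-force Smith-Waterman (Gotoh affine gaps). A gap of length L costs
## gap_open + L * gap_extend, matching the scoring convention of the
## package aligner's backend.
sw_local_oracle <- function(a, b, match = 2, mismatch = -3, gap_open = 6,
                            gap_extend = 1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F_ <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F_[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                      F_[i - 1L, j] - gap_extend)
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## Spearman rho from first principles (mean ranks for ties).
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Expected distinct clonotypes when drawing k reads without replacement
## from counts (multivariate hypergeometric): sum_i 1 - C(N - n_i, k)/C(N, k).
expected_richness_hyper <- function(counts, k) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, k) - lchoose(N, k)))
}

## Exact rank-sum (Mann-Whitney W) null distribution by enumeration.
ranksum_enumeration <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combs <- utils::combn(length(pooled), length(x))
  w_all <- apply(combs, 2L, function(idx) {
    sum(r[idx]) - length(x) * (length(x) + 1) / 2
  })
  p_two <- mean(abs(w_all - mean(w_all)) >= abs(w_obs - mean(w_all)))
  list(statistic = w_obs, p_value = p_two)
}

## Gini by the direct double sum.
gini_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

## Mean silhouette over a 1-D embedding with two groups.
silhouette_1d <- function(values, groups) {
  gs <- unique(groups)
  stopifnot(length(gs) == 2L)
  s <- vapply(seq_along(values), function(i) {
    same <- setdiff(which(groups == groups[i]), i)
    other <- which(groups != groups[i])
    a <- if (length(same)) mean(abs(values[i] - values[same])) else 0
    b <- mean(abs(values[i] - values[other]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
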