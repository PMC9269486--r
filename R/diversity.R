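## Repertoire diversity: index battery, group-wise resampling, Hill
## diversity profiles with clustering, and non-parametric group
## comparisons.

#' Diversity index battery for a clonotype count vector
#'
#' Computes observed richness, Shannon entropy (natural log), normalized
#' Shannon (H / ln S; flagged undefined when S <= 1), inverse Simpson,
#' Chao1 (`S + f1^2 / (2 f2)`, bias-corrected `S + f1 (f1 - 1) / (2 (f2 +
#' 1))` when `f2 == 0`), the Efron-Thisted estimator (Euler-transformed
#' alternating series over the frequency-of-frequencies, fixed depth), d50
#' (minimal number of top clonotypes reaching cumulative frequency 0.5),
#' and the Gini index (`sum_ij |x_i - x_j| / (2 n^2 xbar)`).
#'
#' @param counts integer vector of clonotype counts (zeros dropped)
#' @param et_depth series depth for the Efron-Thisted estimator
#'   (default 20)
#' @return named list of index values; `normalized_shannon` is `NA` when
#'   undefined
#' @export
diversity_indices <- function(counts, et_depth = 20L) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  S <- length(counts)
  p <- counts / n
  H <- -sum(p * log(p))
  norm_H <- if (S > 1L) H / log(S) else NA_real_
  inv_simpson <- 1 / sum(p^2)
  f <- tabulate(counts)
  f1 <- if (length(f) >= 1L) f[1L] else 0L
  f2 <- if (length(f) >= 2L) f[2L] else 0L
  chao1 <- if (f2 > 0L) S + f1^2 / (2 * f2) else
    S + f1 * (f1 - 1) / (2 * (f2 + 1))
  et <- efron_thisted(f, depth = et_depth)
  cum <- cumsum(sort(p, decreasing = TRUE))
  d50 <- which(cum >= 0.5)[1L]
  x <- sort(as.numeric(counts))
  gini <- if (S == 1L) 0 else {
    ## identity: sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
    sum((2 * seq_len(S) - S - 1) * x) / (S^2 * mean(x))
  }
  list(observed = S, shannon = H, normalized_shannon = norm_H,
       inv_simpson = inv_simpson, chao1 = chao1, efron_thisted = et,
       d50 = as.integer(d50), gini = gini)
}

## Efron-Thisted unseen-species estimate: Euler transform of the
## alternating series sum_k (-1)^(k+1) f_k, added to observed richness.
efron_thisted <- function(f, depth = 20L) {
  S <- sum(f)
  k <- min(depth, length(f))
  if (k == 0L) return(as.numeric(S))
  a <- f[seq_len(k)]                      # a_k, series sum_k (-1)^(k+1) a_k
  ## Euler transformation: sum_j Delta^j a_1 / 2^(j+1) with forward
  ## differences of the sequence a_1, a_2, ...
  delta <- as.numeric(a)
  est <- 0
  for (j in seq_len(k)) {
    est <- est + delta[1L] / 2^j
    if (length(delta) == 1L) break
    delta <- diff(delta)
  }
  S + max(0, est)
}

#' Hill diversity profile
#'
#' `D_alpha = (sum p_i^alpha)^(1 / (1 - alpha))` for `alpha != 1`; at
#' `alpha = 1` the continuity limit `exp(H)` is used (a raw-Shannon mode
#' is available). `D_0` is the observed richness and `D_2` the inverse
#' Simpson index.
#'
#' @param freqs clonotype frequencies (renormalized internally)
#' @param alphas grid of orders (default 0 to 10 step 0.2)
#' @param at1 value reported at alpha = 1: `"exp_shannon"` (default,
#'   continuity limit) or `"shannon"` (raw entropy)
#' @return data.frame `alpha`, `hill`
#' @export
hill_profile <- function(freqs, alphas = seq(0, 10, by = 0.2),
                         at1 = c("exp_shannon", "shannon")) {
  at1 <- match.arg(at1)
  p <- freqs[freqs > 0]
  p <- p / sum(p)
  hill <- vapply(alphas, function(a) {
    if (abs(a - 1) < 1e-12) {
      H <- -sum(p * log(p))
      if (at1 == "exp_shannon") exp(H) else H
    } else {
      sum(p^a)^(1 / (1 - a))
    }
  }, numeric(1))
  data.frame(alpha = alphas, hill = hill)
}

#' Group-wise resampled diversity estimates
#'
#' Tables with fewer than `min_clones` clonotypes are excluded. Remaining
#' tables are each down-sampled, at read level and without replacement, to
#' the size of the smallest clone set in the group; indices are recomputed
#' per iteration and summarized as mean and SD.
#'
#' @param tables list of `clonotype_table`s forming one comparison group
#' @param n_iter resampling iterations (default 1000)
#' @param min_clones exclusion threshold on clonotype count (default 100)
#' @param seed RNG seed
#' @param indices index names to report (default all from
#'   [diversity_indices()])
#' @return list with `estimates` (data.frame: sample_id, timepoint, chain,
#'   index, mean, sd, n_resamples, downsample_size) and `excluded`
#'   (data.frame of excluded tables with reasons)
#' @export
resampled_diversity <- function(tables, n_iter = 1000L, min_clones = 100L,
                                seed = 1L,
                                indices = c("observed", "shannon",
                                            "normalized_shannon",
                                            "inv_simpson", "chao1",
                                            "efron_thisted", "d50",
                                            "gini")) {
  n_clones <- vapply(tables, function(t) nrow(t$clonotypes), integer(1))
  excl <- n_clones < min_clones
  excluded <- data.frame(
    sample_id = vapply(tables[excl], `[[`, character(1), "sample_id"),
    n_clones = n_clones[excl],
    reason = rep(sprintf("clones < %d", min_clones), sum(excl)),
    stringsAsFactors = FALSE)
  tables <- tables[!excl]
  if (length(tables) < 2L) {
    stop("fewer than two tables remain after the clone-count exclusion")
  }
  reads <- vapply(tables, function(t) sum(t$clonotypes$count), integer(1))
  k <- min(reads)
  set.seed(seed)
  rows <- list()
  for (t in tables) {
    counts <- t$clonotypes$count
    pool <- rep.int(seq_along(counts), counts)
    acc <- matrix(NA_real_, nrow = n_iter, ncol = length(indices),
                  dimnames = list(NULL, indices))
    for (it in seq_len(n_iter)) {
      draw <- tabulate(pool[sample.int(length(pool), k)],
                       nbins = length(counts))
      vals <- diversity_indices(draw)
      acc[it, ] <- unlist(vals[indices])
    }
    for (ix in indices) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = t$sample_id, timepoint = t$timepoint, chain = t$chain,
        index = ix, mean = mean(acc[, ix]), sd = stats::sd(acc[, ix]),
        n_resamples = n_iter, downsample_size = k,
        stringsAsFactors = FALSE)
    }
  }
  list(estimates = do.call(rbind, rows), excluded = excluded)
}

#' Euclidean distances and complete-linkage clustering of Hill profiles
#'
#' @param profiles samples x alpha-grid matrix of Hill numbers
#' @return list with `dist` and `hclust` (complete linkage)
#' @export
profile_clustering <- function(profiles) {
  d <- stats::dist(profiles)
  list(dist = d, hclust = stats::hclust(d, method = "complete"))
}

#' Rank-based group comparison with Bonferroni correction
#'
#' Uses the Wilcoxon signed-rank test for paired data and the
#' Mann-Whitney-Wilcoxon rank-sum test otherwise; the p-value is adjusted
#' as `min(1, p * m)` for `m` comparisons in the family.
#'
#' @param x,y numeric vectors of per-sample values
#' @param paired paired comparison (default FALSE)
#' @param m number of comparisons in the family (default 1)
#' @return list with `statistic`, `p_value`, `p_adjusted`, `method`
#' @export
group_compare <- function(x, y, paired = FALSE, m = 1L) {
  wt <- stats::wilcox.test(x, y, paired = paired, exact = NULL)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = min(1, wt$p.value * m), method = wt$method)
}
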