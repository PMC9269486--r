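test_that("diversity indices match their closed forms", {
  ## uniform four-clone repertoire
  ix <- diversity_indices(rep(5L, 4L))
  expect_equal(ix$observed, 4L)
  expect_equal(ix$shannon, log(4))
  expect_equal(ix$normalized_shannon, 1)
  expect_equal(ix$inv_simpson, 4)
  expect_equal(ix$gini, 0)
  expect_equal(ix$d50, 2L)
  ## skewed two-clone repertoire
  ix2 <- diversity_indices(c(90L, 10L))
  expect_equal(ix2$inv_simpson, 1 / 0.82, tolerance = 1e-12)
  ## chao1 with S = 10, f1 = 2, f2 = 1: 10 + 4/2 = 12
  counts <- c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 6L, 7L, 8L)
  expect_equal(diversity_indices(counts)$chao1, 12)
  ## chao1 bias-corrected branch when f2 = 0
  counts2 <- c(1L, 1L, 3L, 4L, 5L)
  expect_equal(diversity_indices(counts2)$chao1, 5 + 2 * 1 / 2)
  ## singleton-free sample: estimators do not fall below richness
  expect_gte(diversity_indices(counts)$efron_thisted, 10)
  ## normalized Shannon undefined at S = 1
  expect_true(is.na(diversity_indices(10L)$normalized_shannon))
  ## Gini agrees with the direct double-sum oracle
  set.seed(3)
  x <- sample.int(100L, 30L, replace = TRUE)
  expect_equal(diversity_indices(x)$gini, gini_oracle(x), tolerance = 1e-12)
})

test_that("Shannon and inverse Simpson agree with an independent
           implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (i in 1:5) {
    x <- sample.int(200L, 40L, replace = TRUE)
    ix <- diversity_indices(x)
    expect_equal(ix$shannon, unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-12)
    expect_equal(ix$inv_simpson, unname(vegan::diversity(x, "invsimpson")),
                 tolerance = 1e-12)
  }
})

test_that("Hill profiles satisfy the continuity and special-order
           identities and are non-increasing", {
  ## uniform: D_alpha = S for every alpha
  prof <- hill_profile(rep(0.2, 5))
  expect_equal(prof$hill, rep(5, nrow(prof)), tolerance = 1e-9)
  ## random frequencies
  set.seed(4)
  p <- as.numeric(rmultinom(1, 500, runif(30)))
  p <- p[p > 0] / sum(p)
  prof2 <- hill_profile(p)
  ix <- diversity_indices(as.integer(round(p * 1e6)))
  expect_equal(prof2$hill[prof2$alpha == 0], length(p))
  expect_equal(prof2$hill[prof2$alpha == 2], 1 / sum(p^2),
               tolerance = 1e-9)
  ## D_1 = exp(H), checked against the numerical limit
  d1 <- prof2$hill[prof2$alpha == 1]
  expect_equal(d1, exp(-sum(p * log(p))), tolerance = 1e-12)
  near <- vapply(c(1 - 1e-6, 1 + 1e-6), function(a) {
    sum(p^a)^(1 / (1 - a))
  }, numeric(1))
  expect_lt(max(abs(near - d1) / d1), 1e-6)
  ## monotone non-increasing in alpha
  expect_true(all(diff(prof2$hill) <= 1e-9))
  ## raw-Shannon mode at alpha = 1
  prof3 <- hill_profile(p, at1 = "shannon")
  expect_equal(prof3$hill[prof3$alpha == 1], -sum(p * log(p)))
})

test_that("resampled richness matches the hypergeometric expectation and
           excludes small clone sets", {
  set.seed(21)
  counts <- rep(c(1L, 2L, 5L, 10L), length.out = 1000L)
  big <- make_table(counts, v = sprintf("IGHV1-%d", 1:1000),
                    cdr3 = sprintf("AK%04d", 1:1000), sample_id = "A")
  partner <- make_table(rep(1L, 100L), v = sprintf("IGHV1-%d", 1:100),
                        cdr3 = sprintf("AK%04d", 1:100), sample_id = "B")
  small <- make_table(rep(1L, 99L), v = sprintf("IGHV1-%d", 1:99),
                      cdr3 = sprintf("AK%04d", 1:99), sample_id = "C")
  got <- resampled_diversity(list(big, partner, small), n_iter = 1000L,
                             seed = 5L)
  expect_equal(got$excluded$sample_id, "C")
  est <- got$estimates
  expect_true(all(est$downsample_size == 100L))
  obs <- est[est$sample_id == "A" & est$index == "observed", ]
  expected <- expected_richness_hyper(counts, 100L)
  mc_se <- obs$sd / sqrt(obs$n_resamples)
  expect_lt(abs(obs$mean - expected), 3 * mc_se)
  ## identical tables give equal means within Monte-Carlo error (partner
  ## forces genuine downsampling)
  dup <- resampled_diversity(list(big, big, partner), n_iter = 300L,
                             seed = 9L)
  e <- dup$estimates
  inv <- e[e$index == "inv_simpson" & e$sample_id == "A", ]
  expect_lt(abs(diff(inv$mean)), 3 * sqrt(sum((inv$sd / sqrt(300))^2)))
  ## seed invariance within Monte-Carlo error
  got2 <- resampled_diversity(list(big, partner), n_iter = 500L,
                              seed = 77L)
  obs2 <- got2$estimates
  obs2 <- obs2[obs2$sample_id == "A" & obs2$index == "observed", ]
  expect_lt(abs(obs2$mean - expected), 3 * obs2$sd / sqrt(500))
})

test_that("deeply sequenced uniform repertoires recover the clone count
           through the inverse Simpson index", {
  K <- 50L
  tabs <- lapply(c("A", "B"), function(s) {
    make_table(rep(200L, K), v = sprintf("IGHV1-%d", 1:K),
               cdr3 = sprintf("AK%03d", 1:K), sample_id = s)
  })
  got <- resampled_diversity(tabs, n_iter = 200L, min_clones = 10L,
                             seed = 13L)
  inv <- got$estimates[got$estimates$index == "inv_simpson", ]
  expect_true(all(abs(inv$mean - K) / K < 0.05))
})

test_that("profile clustering is symmetric, zero-diagonal and matches the
           brute-force complete-linkage heights", {
  alphas <- seq(0, 10, by = 0.2)
  p1 <- hill_profile(rep(0.1, 10), alphas)$hill
  p2 <- hill_profile(rep(0.1, 10), alphas)$hill
  p3 <- hill_profile(c(0.9, rep(0.1 / 9, 9)), alphas)$hill
  m <- rbind(a = p1, b = p2, c = p3)
  got <- profile_clustering(m)
  dm <- as.matrix(got$dist)
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  ## complete linkage: first merge a-b at 0, then c at max pairwise
  expect_equal(sort(got$hclust$height),
               sort(c(0, max(dm["a", "c"], dm["b", "c"]))))
})

test_that("group comparisons use rank tests with Bonferroni adjustment", {
  ## identical groups: no evidence of difference (ties force the normal
  ## approximation, which wilcox.test warns about)
  x <- c(1, 2, 3, 4)
  got <- suppressWarnings(group_compare(x, x, paired = FALSE))
  expect_gte(got$p_value, 0.99)
  ## Bonferroni arithmetic
  expect_equal(min(1, 0.04 * 3), 0.12)
  got2 <- group_compare(c(1, 2), c(3, 4), m = 3L)
  expect_equal(got2$p_adjusted, min(1, got2$p_value * 3))
  ## rank-sum statistic and exact p agree with full enumeration on 2x4
  xs <- c(1.3, 2.1)
  ys <- c(0.4, 3.3, 4.8, 5.1)
  got3 <- group_compare(xs, ys)
  oracle <- ranksum_enumeration(xs, ys)
  expect_equal(unname(got3$statistic), oracle$statistic)
  expect_equal(got3$p_value, oracle$p_value)
  ## paired variant uses the signed-rank test
  got4 <- suppressWarnings(group_compare(c(1, 2, 3), c(2, 3, 4),
                                         paired = TRUE))
  expect_match(got4$method, "signed rank")
})
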