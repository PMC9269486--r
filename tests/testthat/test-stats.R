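test_that("segment usage computes weighted and unweighted proportions", {
  tab <- make_table(c(3L, 1L), v = c("IGHV1-1", "IGHV2-1"))
  w <- segment_usage(tab, "V", weighted = TRUE)
  expect_equal(w$proportion[w$gene == "IGHV1-1"], 0.75)
  expect_equal(w$proportion[w$gene == "IGHV2-1"], 0.25)
  u <- segment_usage(tab, "V", weighted = FALSE)
  expect_equal(u$proportion, c(0.5, 0.5))
  expect_equal(sum(w$proportion), 1)
  ## unassigned D is its own category
  tab2 <- make_table(c(2L, 2L))
  tab2$clonotypes$d <- c("IGHD1", NA)
  du <- segment_usage(tab2, "D", weighted = TRUE)
  expect_equal(du$proportion[du$gene == "unassigned"], 0.5)
})

test_that("usage clustering Z-scores genes and puts identical samples at
           distance zero", {
  t1 <- make_table(c(5L, 5L), v = c("IGHV1-1", "IGHV2-1"), sample_id = "A")
  t2 <- make_table(c(5L, 5L), v = c("IGHV1-1", "IGHV2-1"), sample_id = "B")
  t3 <- make_table(c(9L, 1L), v = c("IGHV1-1", "IGHV2-1"), sample_id = "C")
  m <- usage_matrix(list(t1, t2, t3))
  cl <- usage_cluster(m)
  expect_equal(as.matrix(cl$dist)["A_T1", "B_T1"], 0)
  ## constant gene across samples -> all-zero Z column
  m2 <- cbind(m, const = 0.5)
  cl2 <- usage_cluster(m2)
  expect_true(all(cl2$z[, "const"] == 0))
  ## distances match a brute-force computation on the Z matrix
  bf <- sqrt(sum((cl$z["A_T1", ] - cl$z["C_T1", ])^2))
  expect_equal(as.matrix(cl$dist)["A_T1", "C_T1"], bf)
})

test_that("VJ pairing fractions conserve mass and filter strictly above
           the threshold", {
  tab <- make_table(c(1L), v = "IGHV1-1", j = "IGHJ1")
  got <- vj_pairing(tab)
  expect_equal(got$fraction, 1)
  ## 100 clonotypes: one pair at exactly 1% is excluded
  tab2 <- make_table(rep(1L, 100L),
                     v = c(rep("IGHV1-1", 99L), "IGHV9-9"),
                     j = c(rep("IGHJ1", 99L), "IGHJ9"))
  got2 <- vj_pairing(tab2, min_fraction = 0.01)
  expect_false("IGHV9-9" %in% got2$v)
  full <- attr(got2, "full")
  expect_equal(sum(full$fraction), 1)
})

test_that("spectratype averages samples equally and applies the floor", {
  t1 <- make_table(c(2L, 2L), cdr3 = c("AAAAAAAAA", "AAAAAAAAAAA"))
  got1 <- spectratype(t1)
  expect_equal(got1$mean_proportion, c(0.5, 0.5))
  t2 <- make_table(1L, cdr3 = "AAAAAAAAA", sample_id = "B")
  t3 <- make_table(1L, cdr3 = "AAAAAAAAAAA", sample_id = "C")
  got2 <- spectratype(list(t2, t3))
  expect_equal(got2$mean_proportion, c(0.5, 0.5))
  ## order invariance and self-duplication invariance
  got3 <- spectratype(list(t3, t2))
  expect_equal(got2, got3)
  got4 <- spectratype(list(t2, t2))
  expect_equal(got4, spectratype(t2))
  ## rare length below 1e-5 mean is dropped
  counts <- c(199998L, 2L)
  t5 <- make_table(counts, cdr3 = c("AAAAAAAAA", "AAAAAAAAAAA"))
  t6 <- make_table(1L, cdr3 = "AAAAAAAAA", sample_id = "B")
  got5 <- spectratype(list(t5, t6))
  expect_equal(nrow(got5), 1L)  # mean of 1e-5/2 and 0 is below the floor
})

test_that("top clone fractions rank pooled counts and accept fraction
           columns directly", {
  t1 <- make_table(c(95L, 5L), cdr3 = c("QQSLHFPPT", "GQGIQYPFT"))
  got <- top_clone_fractions(t1, n = 1L)
  expect_equal(attr(got, "cumulative"), 0.95)
  ## uniform ten-clone table: top-3 cumulative is 30%
  t2 <- make_table(rep(1L, 10L))
  expect_equal(attr(top_clone_fractions(t2, 3L), "cumulative"), 0.3)
  ## precomputed fraction column is ranked as-is
  df <- data.frame(sequence = c("A", "B", "C"),
                   fraction = c(0.05, 0.2, 0.1))
  got3 <- top_clone_fractions(df, n = 2L)
  expect_equal(got3$sequence, c("B", "C", "A"))
  expect_equal(attr(got3, "cumulative"), 0.3)
  ## pooled fraction across two samples
  tA <- make_table(c(3L, 1L), cdr3 = c("AAA", "BBB"), sample_id = "A")
  tB <- make_table(c(1L, 3L), cdr3 = c("AAA", "BBB"), sample_id = "B")
  gotAB <- top_clone_fractions(list(tA, tB), n = 1L)
  expect_equal(gotAB$fraction, c(0.5, 0.5))
  expect_equal(gotAB$n_samples, c(2L, 2L))
})

test_that("position profiles average per-sample frequencies and expose
           anchor flanks", {
  t1 <- make_table(c(1L, 1L), cdr3 = c("AKFDY", "AKWDY"), sample_id = "A")
  prof <- position_profile(list(t1), "IGH", 5L)
  expect_equal(dim(prof), c(20L, 5L))
  expect_equal(unname(colSums(prof)), rep(1, 5))
  expect_equal(prof["F", 3L], 0.5)
  expect_equal(prof["W", 3L], 0.5)
  expect_equal(prof["A", 1L], 1)
  ## flanks: first column is the conserved cysteine
  proff <- position_profile(list(t1), "IGH", 5L, include_flanks = TRUE)
  expect_equal(proff["C", 1L], 1)
  expect_equal(colnames(proff)[1L], "104")
  ## count weighting within a sample
  t2 <- make_table(c(3L, 1L), cdr3 = c("AKFDY", "AKWDY"), sample_id = "B")
  prof2 <- position_profile(list(t2), "IGH", 5L)
  expect_equal(prof2["F", 3L], 0.75)
})

test_that("logo heights follow the Shannon information closed forms", {
  point <- matrix(0, 20L, 1L, dimnames = list(bcrflow:::AA_ALPHABET, "105"))
  point["W", 1L] <- 1
  h <- logo_heights(point)
  expect_equal(h["W", 1L], log2(20))
  expect_equal(sum(h[, 1L]), attr(h, "information")[[1L]])
  uniform <- matrix(1 / 20, 20L, 1L,
                    dimnames = list(bcrflow:::AA_ALPHABET, "105"))
  expect_equal(sum(logo_heights(uniform)), 0)
  half <- matrix(0, 20L, 1L, dimnames = list(bcrflow:::AA_ALPHABET, "105"))
  half[c("A", "K"), 1L] <- 0.5
  hh <- logo_heights(half)
  expect_equal(hh["A", 1L], (log2(20) - 1) / 2)
})

test_that("biochemical class proportions map amino acids through the
           shipped tables and conserve mass", {
  prof <- matrix(0, 20L, 2L, dimnames = list(bcrflow:::AA_ALPHABET,
                                             c("105", "106")))
  prof["D", 1L] <- 1
  prof["S", 2L] <- 1
  bp <- biochem_profile(prof)
  expect_equal(bp$charge["negative", 1L], 1)
  expect_equal(bp$hydropathy["neutral", 2L], 1)
  for (prop in names(bp)) {
    expect_equal(unname(colSums(bp[[prop]])), rep(1, 2L))
  }
})

test_that("usage correlation excludes rare genes and matches the rank
           oracle", {
  ## two perfectly anticorrelated genes across 6 samples
  usage <- cbind(g1 = seq(0.2, 0.7, by = 0.1),
                 g2 = seq(0.76, 0.26, by = -0.1),
                 rare = rep(0.04, 6))
  rownames(usage) <- paste0("S", 1:6)
  got <- usage_correlation(usage, min_mean_fraction = 0.05)
  expect_equal(nrow(got), 1L)
  expect_equal(got$rho, -1)
  expect_false("rare" %in% c(got$gene_a, got$gene_b))
  ## oracle agreement on random profiles
  set.seed(10)
  m <- matrix(runif(40), nrow = 8L,
              dimnames = list(NULL, paste0("g", 1:5)))
  m <- m / rowSums(m)
  got2 <- usage_correlation(m, min_mean_fraction = 0)
  for (i in seq_len(nrow(got2))) {
    expect_equal(got2$rho[i],
                 spearman_oracle(m[, got2$gene_a[i]], m[, got2$gene_b[i]]),
                 tolerance = 1e-12)
  }
})
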