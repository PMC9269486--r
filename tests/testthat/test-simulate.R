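test_that("germline-identity recombination reproduces the implied CDR3", {
  ref <- toy_ref()
  cfg <- sim_config(seed = 2L, trim_p = 1, n_insert_mean = 0,
                    shm_rate = 0, frameshift_fraction = 0)
  set.seed(7)
  cl <- recombine(ref, "IGH", cfg)
  v <- gene_by_name(ref, cl$v_name)
  j <- gene_by_name(ref, cl$j_name)
  ## junction starts with the full V and ends with the full J
  expect_equal(substr(cl$junction_nt, 1L, nchar(v$sequence)), v$sequence)
  expect_equal(substr(cl$junction_nt,
                      nchar(cl$junction_nt) - nchar(j$sequence) + 1L,
                      nchar(cl$junction_nt)), j$sequence)
  ## CDR3 from the germline anchors matches the reported short CDR3
  anchor_q <- nchar(cl$junction_nt) - nchar(j$sequence) + j$anchor_offset
  cdr3 <- substr(cl$junction_nt, v$anchor_offset + 1L, anchor_q + 3L)
  aa <- translate_nt(cdr3)
  expect_equal(substr(aa, 2L, nchar(aa) - 1L), cl$cdr3_aa_short)
  expect_true(cl$functional)
})

test_that("SHM mutation counts follow the binomial expectation", {
  ref <- toy_ref()
  cfg <- sim_config(seed = 2L, trim_p = 1, n_insert_mean = 0,
                    shm_rate = 0.02, frameshift_fraction = 0)
  set.seed(123)
  n_draw <- 1000L
  muts <- vapply(seq_len(n_draw), function(i) {
    recombine(ref, "IGK", cfg)$n_shm
  }, integer(1))
  v_len <- nchar(get_genes(ref, "IGK", "V")$sequence[1L])
  expected <- v_len * 0.02
  se <- sqrt(v_len * 0.02 * 0.98 / n_draw)
  expect_lt(abs(mean(muts) - expected), 3 * se)
})

test_that("frameshift_fraction = 1 yields only non-functional clones", {
  ref <- toy_ref()
  cfg <- sim_config(seed = 4L, n_clones = 25L, frameshift_fraction = 1,
                    n_molecules = 50L)
  truth <- simulate_repertoire(ref, cfg)
  expect_true(all(!truth$clones$functional))
})

test_that("spike and uniform frequency models hit their molecule shares", {
  ref <- toy_ref()
  cfg <- sim_config(seed = 31L, n_clones = 50L,
                    freq_model = list(type = "spike",
                                      dominant_fraction = 0.954),
                    chain = "IGH", n_molecules = 10000L,
                    frameshift_fraction = 0)
  truth <- simulate_repertoire(ref, cfg)
  share <- mean(truth$molecules$clone_id == "clone0001")
  expect_lt(abs(share - 0.954), 0.01)

  cfg_u <- sim_config(seed = 32L, n_clones = 10L,
                      freq_model = list(type = "uniform"),
                      chain = "IGL", n_molecules = 8000L,
                      frameshift_fraction = 0)
  truth_u <- simulate_repertoire(ref, cfg_u)
  shares <- as.numeric(table(truth_u$molecules$clone_id)) / 8000
  se <- sqrt(0.1 * 0.9 / 8000)
  expect_true(all(abs(shares - 0.1) < 3 * se))
  expect_equal(sum(truth_u$clones$frequency), 1)
})

test_that("UMI collisions follow the birthday-problem expectation", {
  ref <- toy_ref()
  collisions <- vapply(1:8, function(s) {
    cfg <- sim_config(seed = 100L + s, n_clones = 5L, umi_len = 8L,
                      n_molecules = 2000L, frameshift_fraction = 0)
    simulate_repertoire(ref, cfg)$umi_collisions
  }, numeric(1))
  m <- 2000
  ## sparse regime: colliding UMI count ~ Poisson(m(m-1)/2 / 4^8)
  expected <- m * (m - 1) / 2 / 4^8
  se <- sqrt(expected / 8)
  expect_lt(abs(mean(collisions) - expected), 3 * se)
})

test_that("error-free reads substring-match their molecule transcript and
           synthesis is deterministic", {
  run <- small_run()
  d <- withr::local_tempdir()
  paths2 <- synthesize_reads(run$truth, run$ref, run$cfg,
                             file.path(d, "again"))
  expect_identical(readLines(run$paths[["r1"]]), readLines(paths2[["r1"]]))
  expect_identical(readLines(run$paths[["r2"]]), readLines(paths2[["r2"]]))

  ## reconstruct transcripts and check containment for a sample of reads
  cl <- run$truth$clones
  mol <- run$truth$molecules
  cstub <- get_genes(run$ref, segment = "C")
  idx <- seq_len(min(50L, nrow(run$pairs)))
  mol_id <- sub(".*mol=", "", names(Biostrings::readDNAStringSet(
    run$paths[["r1"]], format = "fastq"))[idx])
  for (i in seq_along(idx)) {
    m <- mol[mol$molecule_id == mol_id[i], ]
    tr <- paste0(TSO_TAIL, m$umi,
                 cl$junction_nt[cl$clone_id == m$clone_id],
                 cstub$sequence[cstub$name == m$isotype])
    expect_true(grepl(run$pairs$r1_seq[idx[i]], tr, fixed = TRUE))
    expect_true(grepl(revcomp(run$pairs$r2_seq[idx[i]]), tr, fixed = TRUE))
  }
})

test_that("reads-per-read error rate matches the binomial oracle", {
  ref <- toy_ref()
  cfg <- sim_config(seed = 77L, n_clones = 5L, n_molecules = 400L,
                    reads_per_molecule_mean = 2, seq_error_rate = 0.01,
                    shm_rate = 0, frameshift_fraction = 0)
  truth <- simulate_repertoire(ref, cfg)
  d <- withr::local_tempdir()
  paths <- synthesize_reads(truth, ref, cfg, file.path(d, "err"))
  cfg0 <- cfg; cfg0$seq_error_rate <- 0
  paths0 <- synthesize_reads(truth, ref, cfg0, file.path(d, "clean"))
  r_err <- as.character(Biostrings::readDNAStringSet(paths[["r1"]],
                                                     format = "fastq"))
  r_clean <- as.character(Biostrings::readDNAStringSet(paths0[["r1"]],
                                                       format = "fastq"))
  mism <- sum(bcrflow:::hamming_c(r_err, r_clean))
  n_bases <- sum(nchar(r_clean))
  se <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(mism - n_bases * 0.01), 3 * se)
})

test_that("distinct UMIs per clone track clone frequency", {
  ref <- toy_ref()
  cfg <- sim_config(seed = 55L, n_clones = 20L,
                    freq_model = list(type = "powerlaw", exponent = 1),
                    n_molecules = 10000L, frameshift_fraction = 0)
  truth <- simulate_repertoire(ref, cfg)
  umis_per_clone <- tapply(truth$molecules$umi, truth$molecules$clone_id,
                           function(u) length(unique(u)))
  freqs <- truth$clones$frequency[match(names(umis_per_clone),
                                        truth$clones$clone_id)]
  expect_gt(cor(freqs, as.numeric(umis_per_clone), method = "spearman"),
            0.9)
})
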