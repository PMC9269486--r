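test_that("segment alignment recovers exact and mutated germline genes", {
  ref <- toy_ref()
  vs <- get_genes(ref, "IGH", "V")
  params <- align_params()
  ## exact germline copy: perfect score, zero mismatches
  hit <- align_segment(vs$sequence[1L], vs, params)
  expect_equal(hit$gene, vs$name[1L])
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$score, 2 * nchar(vs$sequence[1L]))
  ## two substitutions still map to the source gene
  s <- vs$sequence[2L]
  substr(s, 10L, 10L) <- if (substr(s, 10L, 10L) == "A") "C" else "A"
  substr(s, 50L, 50L) <- if (substr(s, 50L, 50L) == "G") "T" else "G"
  hit2 <- align_segment(s, vs, params)
  expect_equal(hit2$gene, vs$name[2L])
  expect_equal(hit2$mismatches, 2)
  ## random sequence falls below the score floor
  set.seed(5)
  hit3 <- align_segment(random_dna(1L, 60L), vs, params)
  expect_true(is.na(hit3$gene))
  expect_error(align_segment("", vs, params), "empty")
})

test_that("aligner scores equal the brute-force dynamic-programming oracle", {
  set.seed(99)
  params <- align_params()
  for (i in 1:200) {
    q <- random_dna(1L, sample(15:60, 1L))
    g <- random_dna(1L, sample(15:60, 1L))
    ## plant a shared core in half the instances so scores span the range
    if (i %% 2L == 0L) {
      core <- random_dna(1L, 12L)
      q <- paste0(substr(q, 1L, 10L), core)
      g <- paste0(core, substr(g, 1L, 10L))
    }
    cand <- data.frame(name = "G1", sequence = g, stringsAsFactors = FALSE)
    got <- align_segment(q, cand, params)$score
    expect_equal(got, sw_local_oracle(q, g), tolerance = 1e-9)
  }
})

test_that("D identification needs a long-enough exact match and breaks ties
           by locus order", {
  ds <- data.frame(name = c("IGHD1", "IGHD2"),
                   sequence = c("ACGTACGTACGTAC", "TTGCATGCATGCAA"),
                   stringsAsFactors = FALSE)
  expect_equal(find_d("GGACGTACGTACGTGG", ds, 5L)$gene, "IGHD1")
  expect_true(is.na(find_d("ACG", ds, 5L)$gene))
  expect_true(is.na(find_d("GGGGACGTGGGG", ds, 5L)$gene))  # 4-nt match only
  ## equal-length matches from both genes -> first in locus order
  tie <- paste0("AA", substr(ds$sequence[1L], 1L, 6L), "CCAA",
                substr(ds$sequence[2L], 1L, 6L), "AA")
  expect_equal(find_d(tie, ds, 5L)$gene, "IGHD1")
})

test_that("CDR3 extraction translates anchors correctly and trims a
           leading residue before the cysteine", {
  ## synthetic alignment hits: identity mapping (no gaps)
  mk_hit <- function(seq, q0, s0, len) {
    data.frame(gene = "G", score = 2 * len, q_start = q0, q_end = q0 + len,
               s_start = s0, s_end = s0 + len, mismatches = 0,
               aligned_length = len,
               aligned_pattern = substr(seq, q0 + 1L, q0 + len),
               aligned_subject = substr(seq, q0 + 1L, q0 + len),
               stringsAsFactors = FALSE)
  }
  ## anchored CDR3 "TGT GCC AAA TTT TGG" -> CAKFW, short AKF
  seq <- paste0("TGTGCCAAATTTTGG")
  v_hit <- mk_hit(seq, 0L, 0L, 6L)    # covers Cys codon at gene offset 0
  j_hit <- mk_hit(seq, 9L, 0L, 6L)    # anchor at gene offset 3 -> query 12
  got <- extract_cdr3(seq, v_hit, j_hit, v_anchor = 0L, j_anchor = 3L)
  expect_equal(got$cdr3_aa, "CAKFW")
  expect_equal(got$cdr3_aa_short, "AKF")
  expect_true(got$frame_ok)

  ## anchored sequence beginning GGT TGT ... (X-C): leading residue trimmed
  seq2 <- paste0("GGT", seq)
  v_hit2 <- mk_hit(seq2, 0L, 0L, 9L)
  j_hit2 <- mk_hit(seq2, 12L, 0L, 6L)
  got2 <- extract_cdr3(seq2, v_hit2, j_hit2, v_anchor = 0L, j_anchor = 3L)
  expect_equal(substr(got2$cdr3_aa, 1L, 1L), "C")
  expect_equal(got2$cdr3_aa, "CAKFW")

  ## anchor outside the alignment -> no CDR3
  got3 <- extract_cdr3(seq, mk_hit(seq, 0L, 3L, 3L), j_hit,
                       v_anchor = 0L, j_anchor = 3L)
  expect_null(got3)
})

test_that("functionality requires frame and absence of stop codons", {
  ## in-frame, stop-free
  seq <- "TGTGCCAAATTTTGG"
  got <- classify_functionality(seq, frame_ok = TRUE, q_cys = 0L,
                                q_v_start = 0L, q_j_end = 15L)
  expect_true(got$functional)
  ## frameshift
  expect_false(classify_functionality(seq, frame_ok = FALSE, q_cys = 0L,
                                      q_v_start = 0L,
                                      q_j_end = 15L)$functional)
  ## TAA inside the CDR3
  seq_stop <- "TGTTAAAAATTTTGG"
  got2 <- classify_functionality(seq_stop, frame_ok = TRUE, q_cys = 0L,
                                 q_v_start = 0L, q_j_end = 15L)
  expect_false(got2$functional)
  expect_true(got2$has_stop)
})

test_that("V mutation counts recover planted substitutions and the
           binomial SHM expectation", {
  ref <- toy_ref()
  vs <- get_genes(ref, "IGL", "V")
  params <- align_params()
  ## exact copy: zero mutations
  hit0 <- align_segment(vs$sequence[1L], vs, params)
  expect_equal(count_v_mutations(hit0)$v_mutations, 0)
  ## two planted substitutions: exactly two
  s <- vs$sequence[1L]
  for (p in c(30L, 90L)) {
    substr(s, p, p) <- if (substr(s, p, p) == "A") "G" else "A"
  }
  hit2 <- align_segment(s, vs, params)
  expect_equal(count_v_mutations(hit2)$v_mutations, 2)

  ## simulator SHM at rate 0.01 recovered by annotation, 300 clones
  cfg <- sim_config(seed = 8L, trim_p = 1, n_insert_mean = 0,
                    shm_rate = 0.01, frameshift_fraction = 0)
  set.seed(42)
  clones <- do.call(rbind, lapply(1:300, function(i) {
    recombine(ref, "IGL", cfg)
  }))
  hits <- align_segment(clones$junction_nt, vs, params)
  muts <- vapply(seq_len(nrow(hits)), function(i) {
    count_v_mutations(hits[i, ])$v_mutations
  }, numeric(1))
  v_len <- nchar(vs$sequence[1L])
  se <- sqrt(v_len * 0.01 * 0.99 / 300)
  expect_lt(abs(mean(muts) - v_len * 0.01), 3 * se)
})

test_that("error-free annotation recovers truth exactly and enforces the
           CDR3 drop rule", {
  run <- small_run()
  ann <- run$ann$annotations
  expect_true(all(!is.na(ann$v_gene) & !is.na(ann$j_gene) &
                    !is.na(ann$cdr3_aa_short)))
  ## every consensus maps back to its true clone's V/J/CDR3
  cl <- run$truth$clones
  mol <- run$truth$molecules
  key <- paste(mol$isotype, mol$umi, sep = ":")
  mig_ids <- run$pp$consensus$mig_id[match(
    paste(ann$isotype, ann$umi, sep = ":"), paste(run$pp$consensus$isotype,
                                                  run$pp$consensus$umi,
                                                  sep = ":"))]
  clone_of <- cl[match(mol$clone_id[match(mig_ids, key)], cl$clone_id), ]
  expect_equal(ann$v_gene, clone_of$v_name)
  expect_equal(ann$j_gene, clone_of$j_name)
  expect_equal(ann$cdr3_aa_short, clone_of$cdr3_aa_short)
})
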