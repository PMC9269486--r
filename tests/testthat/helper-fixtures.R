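## Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

toy_ref <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- build_toy_reference(seed = 42L)
  }
  .fixture_env$ref
}

## A small end-to-end simulated IGH dataset shared by pipeline-level tests.
small_run <- function() {
  if (is.null(.fixture_env$run)) {
    ref <- toy_ref()
    cfg <- sim_config(seed = 11L, n_clones = 15L,
                      freq_model = list(type = "uniform"), chain = "IGH",
                      n_molecules = 250L, reads_per_molecule_mean = 4,
                      seq_error_rate = 0, shm_rate = 0,
                      frameshift_fraction = 0)
    truth <- simulate_repertoire(ref, cfg)
    dir <- file.path(tempdir(), "bcrflow-small-run")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- synthesize_reads(truth, ref, cfg, file.path(dir, "small"))
    pairs <- read_fastq_pairs(paths["r1"], paths["r2"])
    pp <- preprocess_reads(pairs, ref)
    ann <- annotate_consensus(pp$consensus, ref)
    tab <- assemble_clonotypes(ann$annotations, "S1", "T1", "IGH")
    .fixture_env$run <- list(ref = ref, cfg = cfg, truth = truth,
                             paths = paths, pairs = pairs, pp = pp,
                             ann = ann, tab = tab)
  }
  .fixture_env$run
}

## Quick hand-built clonotype tables for the statistics modules.
make_table <- function(counts, v = NULL, j = NULL, cdr3 = NULL,
                       sample_id = "S1", timepoint = "T1",
                       chain = "IGH", ...) {
  n <- length(counts)
  if (is.null(v)) v <- sprintf("IGHV1-%d", seq_len(n))
  if (is.null(j)) j <- rep("IGHJ1", n)
  if (is.null(cdr3)) cdr3 <- sprintf("CDR%04d", seq_len(n))
  clonotype_table(v = v, j = j, cdr3aa = cdr3, count = counts,
                  sample_id = sample_id, timepoint = timepoint,
                  chain = chain, ...)
}
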