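## End-to-end orchestration: simulate (optionally), pre-process, annotate,
## assemble clonotypes, QC, and run the downstream statistics, writing one
## TSV per stage under the output directory.

#' Build and validate a pipeline configuration
#'
#' Defaults are the analysis constants used throughout: MIG size 3, 70%
#' merge similarity, 20-nt minimum overlap, QC thresholds of 1,000 reads
#' and 95% unassigned, a 100-clone floor for diversity resampling with
#' 1,000 iterations, and the 0-10 (step 0.2) Hill alpha grid.
#'
#' @param config named list or path to a YAML document; entries override
#'   the defaults. `samples` is a list of per-sample entries with
#'   `sample_id`, `timepoint`, and either `r1`/`r2` FASTQ paths or a
#'   `simulate` block of [sim_config()] arguments.
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, reference = list(toy = list(seed = 1L)),
                   samples = list(),
                   umi = list(min_mig_size = 3L, merge_similarity = 0.70,
                              min_overlap = 20L, max_mismatch = 2L,
                              umi_len = 8L),
                   annotation = list(match = 2, mismatch = -3,
                                     gap_open = 6, gap_extend = 1,
                                     score_floor_frac = 0.4,
                                     d_min_match = 5L),
                   qc = list(min_reads = 1000L, max_unassigned_pct = 95),
                   diversity = list(n_iter = 1000L, min_clones = 100L,
                                    alpha_max = 10, alpha_step = 0.2))
  samples <- if (is.null(config$samples)) list() else config$samples
  cfg <- utils::modifyList(defaults,
                           config[setdiff(names(config), "samples")])
  cfg$samples <- samples
  if (cfg$umi$merge_similarity <= 0 || cfg$umi$merge_similarity > 1) {
    stop("merge_similarity must be in (0, 1]")
  }
  if (cfg$umi$min_mig_size < 1L) stop("min_mig_size must be positive")
  if (cfg$qc$min_reads < 1L) stop("min_reads must be positive")
  if (cfg$diversity$n_iter < 1L) stop("n_iter must be positive")
  structure(cfg, class = "pipeline_config")
}

load_pipeline_reference <- function(cfg) {
  r <- cfg$reference
  if (!is.null(r$fasta)) {
    if (!file.exists(r$fasta) || !file.exists(r$anchors)) {
      stop("reference files not found: ", r$fasta, " / ", r$anchors)
    }
    load_reference(r$fasta, r$anchors)
  } else {
    do.call(build_toy_reference, r$toy)
  }
}

#' Run the full pipeline
#'
#' Deterministic for a fixed configuration seed. Every stage writes its
#' table under `out_dir`; the returned object carries the in-memory
#' results.
#'
#' @param config a `pipeline_config`, list, or YAML path
#' @param out_dir output directory (created)
#' @return list with `tables` (included `clonotype_table`s), `qc`,
#'   `attrition`, `diversity`, `overlap`, `features`, `pca`, `out_dir`
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (!length(cfg$samples)) stop("config lists no samples")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- load_pipeline_reference(cfg)

  all_tables <- list()
  qc_rows <- list()
  attr_rows <- list()
  for (s in cfg$samples) {
    if (is.null(s$sample_id)) stop("every sample needs a sample_id")
    tp <- if (is.null(s$timepoint)) "T1" else s$timepoint
    if (!is.null(s$simulate)) {
      sim <- do.call(sim_config, s$simulate)
      truth <- simulate_repertoire(ref, sim)
      prefix <- file.path(out_dir, paste0(s$sample_id, "_", tp))
      paths <- synthesize_reads(truth, ref, sim, prefix)
      r1 <- paths["r1"]; r2 <- paths["r2"]
      umi_len <- sim$umi_len
    } else {
      if (is.null(s$r1) || !file.exists(s$r1) || !file.exists(s$r2)) {
        stop("sample ", s$sample_id, ": FASTQ inputs missing")
      }
      r1 <- s$r1; r2 <- s$r2
      umi_len <- cfg$umi$umi_len
    }
    pairs <- read_fastq_pairs(r1, r2)
    pp <- preprocess_reads(pairs, ref,
                           min_mig_size = cfg$umi$min_mig_size,
                           min_similarity = cfg$umi$merge_similarity,
                           min_overlap = cfg$umi$min_overlap,
                           max_mismatch = cfg$umi$max_mismatch,
                           umi_len = umi_len)
    ap <- align_params(cfg$annotation$match, cfg$annotation$mismatch,
                       cfg$annotation$gap_open, cfg$annotation$gap_extend,
                       cfg$annotation$score_floor_frac)
    ann <- annotate_consensus(pp$consensus, ref, ap,
                              d_min_match = cfg$annotation$d_min_match)
    for (ch in unique(isotype_chain(pp$consensus$isotype))) {
      tab <- assemble_clonotypes(ann$annotations, s$sample_id, tp, ch)
      n_cons <- sum(isotype_chain(pp$consensus$isotype) == ch)
      n_assigned <- tab$totals$assigned
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, timepoint = tp, chain = ch,
        reads = n_cons,
        pct_unassigned = if (n_cons == 0L) 100 else
          100 * (n_cons - n_assigned) / n_cons,
        stringsAsFactors = FALSE)
      all_tables[[paste(s$sample_id, tp, ch, sep = "_")]] <- tab
      with_cdr3 <- ann$log$with_cdr3[ann$log$chain == ch]
      aligned <- ann$log$aligned[ann$log$chain == ch]
      attr_rows[[length(attr_rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, timepoint = tp, chain = ch,
        raw_reads = unname(pp$attrition["raw_reads"]),
        isotype_assigned = unname(pp$attrition["isotype_assigned"]),
        umi_extracted = unname(pp$attrition["umi_extracted"]),
        reads_in_kept_migs = unname(pp$attrition["reads_in_kept_migs"]),
        consensus_count = n_cons,
        aligned = if (length(aligned)) aligned else 0L,
        with_cdr3 = if (length(with_cdr3)) with_cdr3 else 0L,
        clonotypes = nrow(tab$clonotypes) + nrow(tab$nonfunctional),
        functional_clonotypes = nrow(tab$clonotypes),
        stringsAsFactors = FALSE)
    }
  }
  qc <- qc_filter(do.call(rbind, qc_rows), cfg$qc$min_reads,
                  cfg$qc$max_unassigned_pct)
  attrition <- do.call(rbind, attr_rows)
  utils::write.table(qc, file.path(out_dir, "qc_decisions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attrition, file.path(out_dir, "attrition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  included <- all_tables[qc$include]
  for (nm in names(all_tables)) {
    write_clonotype_table(all_tables[[nm]],
                          file.path(out_dir, paste0(nm, "_clonotypes.tsv")))
  }

  diversity <- NULL
  alphas <- seq(0, cfg$diversity$alpha_max, by = cfg$diversity$alpha_step)
  profiles <- NULL
  if (length(included) >= 2L) {
    by_chain <- split(included,
                      vapply(included, `[[`, character(1), "chain"))
    div_rows <- list()
    for (grp in by_chain) {
      if (length(grp) < 2L) next
      rd <- try(resampled_diversity(grp, n_iter = cfg$diversity$n_iter,
                                    min_clones = cfg$diversity$min_clones,
                                    seed = cfg$seed), silent = TRUE)
      if (!inherits(rd, "try-error")) {
        div_rows[[length(div_rows) + 1L]] <- rd$estimates
      }
    }
    if (length(div_rows)) {
      diversity <- do.call(rbind, div_rows)
      utils::write.table(diversity, file.path(out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    profiles <- t(vapply(included, function(t) {
      hill_profile(t$clonotypes$freq, alphas)$hill
    }, numeric(length(alphas))))
    rownames(profiles) <- names(included)
    utils::write.table(
      data.frame(sample = rownames(profiles), profiles,
                 check.names = FALSE),
      file.path(out_dir, "hill_profiles.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  overlaps <- list()
  ids <- vapply(included, `[[`, character(1), "sample_id")
  chs <- vapply(included, `[[`, character(1), "chain")
  tps <- vapply(included, `[[`, character(1), "timepoint")
  for (id in unique(ids)) {
    for (ch in unique(chs[ids == id])) {
      sel <- which(ids == id & chs == ch)
      if (length(sel) == 2L) {
        sel <- sel[order(tps[sel])]
        overlaps[[paste(id, ch, sep = "_")]] <-
          overlap_pair(included[[sel[1L]]], included[[sel[2L]]])
      }
    }
  }

  features <- NULL
  pca <- NULL
  feats <- lapply(included, function(t) {
    tryCatch(compute_features(t, diversity), warning = function(w) NULL,
             error = function(e) NULL)
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  if (length(feats) >= 3L) {
    features <- do.call(rbind, feats)
    rownames(features) <- NULL
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    by_chain <- split(seq_len(nrow(features)), features$chain)
    pca <- list()
    for (ch in names(by_chain)) {
      idx <- by_chain[[ch]]
      if (length(idx) >= 3L) {
        p <- try(repertoire_pca(features[idx, , drop = FALSE]),
                 silent = TRUE)
        if (!inherits(p, "try-error")) pca[[ch]] <- p
      }
    }
    if (!length(pca)) pca <- NULL
  }

  invisible(list(tables = all_tables, included = included, qc = qc,
                 attrition = attrition, diversity = diversity,
                 hill_profiles = profiles, overlap = overlaps,
                 features = features, pca = pca, out_dir = out_dir))
}

#' Plain-text summary report of a pipeline run
#'
#' @param result return value of [run_pipeline()] (or an output directory
#'   containing its TSVs)
#' @return character vector of report lines, invisibly (also printed)
#' @export
pipeline_report <- function(result) {
  if (is.character(result)) {
    qc <- utils::read.delim(file.path(result, "qc_decisions.tsv"))
    lines <- c("pipeline report", sprintf("  datasets: %d", nrow(qc)))
    excl <- qc[!qc$include, , drop = FALSE]
    for (i in seq_len(nrow(excl))) {
      lines <- c(lines, sprintf("  EXCLUDED %s %s %s: %s",
                                excl$sample_id[i], excl$timepoint[i],
                                excl$chain[i], excl$reason[i]))
    }
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  qc <- result$qc
  lines <- c("pipeline report",
             sprintf("  datasets processed: %d (included: %d)",
                     nrow(qc), sum(qc$include)))
  if (nrow(qc) == 0L) lines <- c(lines, "  no samples")
  for (i in seq_len(nrow(qc))) {
    nm <- paste(qc$sample_id[i], qc$timepoint[i], qc$chain[i], sep = "_")
    if (qc$include[i]) {
      tab <- result$tables[[nm]]
      lines <- c(lines, sprintf(
        "  %s: %d reads, %d functional clonotypes (top %.1f%%)",
        nm, qc$reads[i], nrow(tab$clonotypes),
        100 * max(c(0, tab$clonotypes$freq))))
    } else {
      lines <- c(lines, sprintf("  %s: EXCLUDED (%s)", nm, qc$reason[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
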