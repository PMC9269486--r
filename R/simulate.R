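## Synthetic repertoire and read simulator.
##
## The generator emits ground truth (clones and molecules) alongside
## UMI-tagged paired-end reads so every downstream stage can be checked
## against known answers. The read layout mirrors a 5'RACE library: the
## forward mate starts with the template-switch oligo (TSO) tail followed
## by the UMI and the 5' end of the V(D)J insert; the reverse mate starts
## inside the isotype's constant region and reads back across the J-C
## boundary into the CDR3.

#' TSO tail preceding the UMI on the forward mate
#' @export
TSO_TAIL <- "AAGCAGTGGTATCAACGCAGAGT"

#' Build and validate a simulation configuration
#'
#' @param seed RNG seed
#' @param n_clones number of clones in the repertoire
#' @param freq_model clone frequency model: `list(type = "uniform")`,
#'   `list(type = "powerlaw", exponent = e)` (frequency of the i-th clone
#'   proportional to i^-e), or `list(type = "spike", dominant_fraction = f)`
#'   (one dominant clone at fraction f, remainder uniform)
#' @param chain chain to simulate: "IGH", "IGK", "IGL", or "light"
#'   (each clone drawn IGL with probability `chain_mix`, else IGK)
#' @param chain_mix lambda fraction among light-chain clones (default 0.91,
#'   the lambda bias reported for dogs)
#' @param isotype_mix heavy-chain isotype proportions (IGM/IGG/IGA/IGE)
#' @param v_usage_bias,j_usage_bias optional named weight vectors over genes
#' @param trim_p geometric parameter for exonuclease trimming at the 3'V,
#'   5'J and both D ends
#' @param n_insert_mean Poisson mean for non-templated N additions per
#'   junction
#' @param shm_rate per-base somatic hypermutation substitution rate in the
#'   V region
#' @param n_molecules number of cDNA molecules
#' @param reads_per_molecule_mean mean of the zero-truncated Poisson
#'   read-count distribution per molecule
#' @param seq_error_rate per-base sequencing error probability
#' @param umi_len UMI length (default 8)
#' @param read_len bases per mate (default 250)
#' @param frameshift_fraction fraction of clones generated out of frame
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_clones = 100L,
                       freq_model = list(type = "powerlaw", exponent = 1),
                       chain = "IGH", chain_mix = 0.91,
                       isotype_mix = c(IGM = 0.45, IGG = 0.35,
                                       IGA = 0.15, IGE = 0.05),
                       v_usage_bias = NULL, j_usage_bias = NULL,
                       trim_p = 0.5, n_insert_mean = 4,
                       shm_rate = 0.01, n_molecules = 5000L,
                       reads_per_molecule_mean = 4,
                       seq_error_rate = 0.001, umi_len = 8L,
                       read_len = 250L, frameshift_fraction = 0.05) {
  stopifnot(n_clones >= 1L, umi_len >= 4L, n_molecules >= 1L,
            read_len >= 50L, reads_per_molecule_mean >= 1)
  check_prob(chain_mix, "chain_mix")
  check_prob(trim_p, "trim_p")
  check_prob(shm_rate, "shm_rate")
  check_prob(seq_error_rate, "seq_error_rate")
  check_prob(frameshift_fraction, "frameshift_fraction")
  if (!chain %in% c(CHAINS, "light")) stop("unknown chain: ", chain)
  if (!freq_model$type %in% c("uniform", "powerlaw", "spike")) {
    stop("unknown freq_model type: ", freq_model$type)
  }
  if (freq_model$type == "spike") {
    f <- freq_model$dominant_fraction
    if (is.null(f) || f <= 0 || f >= 1) {
      stop("spike dominant_fraction must be in (0, 1)")
    }
  }
  if (freq_model$type == "powerlaw" && is.null(freq_model$exponent)) {
    stop("powerlaw freq_model needs an exponent")
  }
  isotype_mix <- isotype_mix / sum(isotype_mix)
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 freq_model = freq_model, chain = chain,
                 chain_mix = chain_mix, isotype_mix = isotype_mix,
                 v_usage_bias = v_usage_bias, j_usage_bias = j_usage_bias,
                 trim_p = trim_p, n_insert_mean = n_insert_mean,
                 shm_rate = shm_rate, n_molecules = as.integer(n_molecules),
                 reads_per_molecule_mean = reads_per_molecule_mean,
                 seq_error_rate = seq_error_rate,
                 umi_len = as.integer(umi_len),
                 read_len = as.integer(read_len),
                 frameshift_fraction = frameshift_fraction),
            class = "sim_config")
}

## Somatic hypermutation over an in-frame V segment. Substitution targets
## that would create an in-frame stop codon are avoided (stop-bearing V
## regions are not expressed as functional receptors), which keeps the
## per-base mutation count binomial at `rate`.
apply_shm <- function(vseg, rate) {
  if (rate <= 0) return(list(seq = vseg, n = 0L))
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(vseg, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  n <- 0L
  for (p in hit) {
    cstart <- ((p - 1L) %/% 3L) * 3L + 1L
    alts <- setdiff(bases, chars[p])
    if (cstart + 2L <= length(chars)) {
      codon <- chars[cstart:(cstart + 2L)]
      pos_in <- p - cstart + 1L
      alts <- alts[vapply(alts, function(b) {
        codon[pos_in] <- b
        !(paste(codon, collapse = "") %in% STOP_CODONS)
      }, logical(1))]
    }
    if (!length(alts)) next
    chars[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    n <- n + 1L
  }
  list(seq = paste(chars, collapse = ""), n = n)
}

clone_frequencies <- function(freq_model, n_clones) {
  switch(freq_model$type,
    uniform = rep(1 / n_clones, n_clones),
    powerlaw = {
      w <- seq_len(n_clones)^(-freq_model$exponent)
      w / sum(w)
    },
    spike = {
      f <- freq_model$dominant_fraction
      if (n_clones == 1L) 1 else c(f, rep((1 - f) / (n_clones - 1L),
                                          n_clones - 1L))
    })
}

gene_weights <- function(genes, bias) {
  w <- rep(1, nrow(genes))
  if (!is.null(bias)) {
    hit <- match(genes$name, names(bias))
    w[!is.na(hit)] <- bias[hit[!is.na(hit)]]
  }
  w / sum(w)
}

## Draw a single V(D)J junction for one clone. Uses the current RNG stream.
#' Recombine one clone from germline segments
#'
#' Junction structure: `V[0 : cys_end + k - trimV] + N1 + (trimmed D + N2
#' for IGH) + J[trimJ : ]`, with somatic hypermutation applied to the V
#' portion. The CDR3 is computed from the reference anchor coordinates
#' mapped through the junction. Trimming never destroys an anchor codon;
#' draws producing a non-functional junction are resampled (bounded) unless
#' the clone is designated out-of-frame.
#'
#' @param ref a `germline_reference`
#' @param chain IGH/IGK/IGL
#' @param config a `sim_config`
#' @param force_nonfunctional generate a frameshifted clone
#' @return one-row data.frame describing the clone (a `TrueClone` row)
#' @export
recombine <- function(ref, chain, config, force_nonfunctional = FALSE) {
  vs <- get_genes(ref, chain, "V", functional_only = TRUE)
  js <- get_genes(ref, chain, "J", functional_only = TRUE)
  ds <- if (chain == "IGH") get_genes(ref, chain, "D") else NULL
  if (nrow(vs) == 0L || nrow(js) == 0L) {
    stop("chain ", chain, " lacks V or J genes")
  }
  for (attempt in seq_len(50L)) {
    v <- vs[sample.int(nrow(vs), 1L, prob = gene_weights(vs, config$v_usage_bias)), ]
    j <- js[sample.int(nrow(js), 1L, prob = gene_weights(js, config$j_usage_bias)), ]
    v_keep_max <- nchar(v$sequence)
    ## trimming is capped so the Cys codon survives in full
    trim_v <- min(stats::rgeom(1L, config$trim_p),
                  v_keep_max - (v$anchor_offset + 3L))
    trim_j <- min(stats::rgeom(1L, config$trim_p), j$anchor_offset)
    v_part <- substr(v$sequence, 1L, v_keep_max - trim_v)
    j_part <- substr(j$sequence, trim_j + 1L, nchar(j$sequence))
    n1 <- stats::rpois(1L, config$n_insert_mean)
    d_part <- ""
    n2 <- 0L
    d_name <- NA_character_
    if (!is.null(ds) && nrow(ds) > 0L) {
      d <- ds[sample.int(nrow(ds), 1L), ]
      trim_d5 <- min(stats::rgeom(1L, config$trim_p), nchar(d$sequence))
      trim_d3 <- min(stats::rgeom(1L, config$trim_p),
                     nchar(d$sequence) - trim_d5)
      d_part <- substr(d$sequence, trim_d5 + 1L, nchar(d$sequence) - trim_d3)
      d_name <- d$name
      n2 <- stats::rpois(1L, config$n_insert_mean)
    }
    cdr3_nt_len <- function(extra_n1) {
      (nchar(v_part) - v$anchor_offset) + n1 + extra_n1 + nchar(d_part) +
        n2 + (j$anchor_offset - trim_j) + 3L
    }
    extra <- 0L
    if (force_nonfunctional) {
      ## break the reading frame of the anchored CDR3 by one N nucleotide
      while (cdr3_nt_len(extra) %% 3L == 0L) extra <- extra + 1L
    } else {
      ## pad N1 so the anchored CDR3 stays in frame
      extra <- (3L - cdr3_nt_len(0L) %% 3L) %% 3L
    }
    n1_seq <- if (n1 + extra > 0L) random_dna(1L, n1 + extra) else ""
    n2_seq <- if (n2 > 0L) random_dna(1L, n2) else ""
    junction <- paste0(v_part, n1_seq, d_part, n2_seq, j_part)
    ## SHM over the V-derived portion only
    n_shm <- 0L
    if (config$shm_rate > 0) {
      shm <- apply_shm(substr(junction, 1L, nchar(v_part)),
                       config$shm_rate)
      n_shm <- shm$n
      junction <- paste0(shm$seq, substr(junction, nchar(v_part) + 1L,
                                         nchar(junction)))
    }
    anchor_pos <- nchar(v_part) + n1 + extra + nchar(d_part) + n2 +
      (j$anchor_offset - trim_j)
    cdr3_nt <- substr(junction, v$anchor_offset + 1L, anchor_pos + 3L)
    frame_ok <- nchar(cdr3_nt) %% 3L == 0L
    aa_full <- translate_nt(substr(junction, 1L, nchar(junction)))
    has_stop <- grepl("*", aa_full, fixed = TRUE)
    functional <- frame_ok && !has_stop
    cdr3_aa <- if (frame_ok) {
      full <- translate_nt(cdr3_nt)
      substr(full, 2L, nchar(full) - 1L)
    } else NA_character_
    if (force_nonfunctional && functional) next
    if (!force_nonfunctional && !functional) next
    return(data.frame(chain = chain, v_name = v$name, d_name = d_name,
                      j_name = j$name, junction_nt = junction,
                      cdr3_aa_short = cdr3_aa, functional = functional,
                      n_shm = as.integer(n_shm),
                      v_part_len = nchar(v_part),
                      stringsAsFactors = FALSE))
  }
  stop("failed to draw a junction with the required functionality for ",
       chain)
}

#' Simulate a ground-truth repertoire
#'
#' Draws `n_clones` clones with frequencies from the configured frequency
#' model, assigns `n_molecules` molecules to clones multinomially, gives
#' every molecule an independent uniform-random UMI (collisions permitted
#' and reported), and draws reads per molecule from a zero-truncated
#' Poisson.
#'
#' @param ref a `germline_reference`
#' @param config a `sim_config`
#' @return list of class `ground_truth` with elements `clones` (one row per
#'   clone incl. target `frequency`), `molecules` (molecule_id, clone_id,
#'   umi, isotype, n_reads) and `umi_collisions` (count of distinct UMI
#'   strings shared by more than one molecule)
#' @export
simulate_repertoire <- function(ref, config) {
  set.seed(config$seed)
  n <- config$n_clones
  freqs <- clone_frequencies(config$freq_model, n)
  chains <- if (config$chain == "light") {
    ifelse(stats::runif(n) < config$chain_mix, "IGL", "IGK")
  } else rep(config$chain, n)
  nonfunc <- stats::runif(n) < config$frameshift_fraction
  clones <- do.call(rbind, lapply(seq_len(n), function(i) {
    recombine(ref, chains[i], config, force_nonfunctional = nonfunc[i])
  }))
  clones <- cbind(clone_id = sprintf("clone%04d", seq_len(n)), clones,
                  frequency = freqs, stringsAsFactors = FALSE)
  counts <- as.integer(stats::rmultinom(1L, config$n_molecules, freqs))
  clone_of_mol <- rep(seq_len(n), counts)
  m <- length(clone_of_mol)
  isotype <- ifelse(clones$chain[clone_of_mol] == "IGH",
                    sample(names(config$isotype_mix), m, replace = TRUE,
                           prob = config$isotype_mix),
                    clones$chain[clone_of_mol])
  umis <- random_dna(m, config$umi_len)
  molecules <- data.frame(
    molecule_id = sprintf("mol%06d", seq_len(m)),
    clone_id = clones$clone_id[clone_of_mol],
    umi = umis, isotype = isotype,
    n_reads = rztpois(m, config$reads_per_molecule_mean),
    stringsAsFactors = FALSE)
  structure(list(clones = clones, molecules = molecules,
                 umi_collisions = sum(table(umis) > 1L),
                 config = config),
            class = "ground_truth")
}

## Full transcript for each molecule: TSO tail + UMI + junction + C stub.
molecule_transcripts <- function(truth, ref) {
  cl <- truth$clones
  mol <- truth$molecules
  cstub <- stats::setNames(get_genes(ref, segment = "C")$sequence,
                           get_genes(ref, segment = "C")$name)
  junction <- cl$junction_nt[match(mol$clone_id, cl$clone_id)]
  paste0(TSO_TAIL, mol$umi, junction, cstub[mol$isotype])
}

#' Synthesize paired-end FASTQ reads from a ground-truth repertoire
#'
#' R1 is the first `read_len` bases of the transcript (TSO tail + UMI +
#' 5' of the insert); R2 is the reverse complement of the last `read_len`
#' bases (constant region back across the J-C boundary into the CDR3).
#' Per-base substitution errors are applied independently per read. FASTQ
#' headers carry the molecule id for debugging only; the pipeline never
#' reads them.
#'
#' @param truth a `ground_truth`
#' @param ref the `germline_reference` used to simulate it
#' @param config the `sim_config`
#' @param out_prefix path prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq`, `<prefix>_clones.tsv`, `<prefix>_molecules.tsv`
#' @return named character vector of the four output paths
#' @export
synthesize_reads <- function(truth, ref, config, out_prefix) {
  set.seed(config$seed + 1L)
  transcripts <- molecule_transcripts(truth, ref)
  min_len <- min(nchar(transcripts))
  ## both mates must reach the CDR3: R1 must clear the TSO+UMI+V, R2 the C
  if (config$read_len <= nchar(TSO_TAIL) + config$umi_len + 60L) {
    stop("read_len too short to reach the CDR3 from either end")
  }
  mol <- truth$molecules
  reps <- rep(seq_len(nrow(mol)), mol$n_reads)
  tr <- transcripts[reps]
  lens <- nchar(tr)
  r1 <- substr(tr, 1L, pmin(config$read_len, lens))
  r2 <- revcomp(substr(tr, pmax(1L, lens - config$read_len + 1L), lens))
  r1 <- apply_substitutions(r1, config$seq_error_rate)
  r2 <- apply_substitutions(r2, config$seq_error_rate)
  ids <- sprintf("read%07d mol=%s", seq_along(tr), mol$molecule_id[reps])
  paths <- c(r1 = paste0(out_prefix, "_R1.fastq"),
             r2 = paste0(out_prefix, "_R2.fastq"),
             clones = paste0(out_prefix, "_clones.tsv"),
             molecules = paste0(out_prefix, "_molecules.tsv"))
  write_fastq(ids, r1, paths["r1"])
  write_fastq(ids, r2, paths["r2"])
  utils::write.table(truth$clones, paths["clones"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$molecules, paths["molecules"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
}

#' Clonotype table implied by a ground-truth repertoire
#'
#' Builds the clonotype table an ideal, loss-free pipeline would recover:
#' counts are molecule counts per clone, collapsed by the (V, J, short
#' CDR3) key, with the simulator's somatic-hypermutation counts carried as
#' V-region mutation data. Useful as the oracle for recovery tests and for
#' feature analyses that do not need read-level noise.
#'
#' @param truth a `ground_truth`
#' @param sample_id,timepoint labels for the table
#' @param chain chain to extract (default: the single simulated chain)
#' @return a `clonotype_table` (functional clones only)
#' @export
truth_clonotype_table <- function(truth, sample_id = "truth",
                                  timepoint = "T1", chain = NULL) {
  cl <- truth$clones
  if (is.null(chain)) {
    chain <- unique(cl$chain)
    if (length(chain) > 1L) stop("multiple chains; specify one")
  }
  mol_counts <- table(truth$molecules$clone_id)
  cl$n_molecules <- as.integer(mol_counts[cl$clone_id])
  cl$n_molecules[is.na(cl$n_molecules)] <- 0L
  cl <- cl[cl$chain == chain & cl$functional & cl$n_molecules > 0L, ,
           drop = FALSE]
  if (nrow(cl) == 0L) stop("no functional molecules for chain ", chain)
  key <- paste(cl$v_name, cl$j_name, cl$cdr3_aa_short, sep = "|")
  idx <- split(seq_len(nrow(cl)), key)
  rows <- lapply(idx, function(i) {
    data.frame(v = cl$v_name[i[1L]], j = cl$j_name[i[1L]],
               cdr3aa = cl$cdr3_aa_short[i[1L]],
               cdr3aa_anchored = paste0("C", cl$cdr3_aa_short[i[1L]], "W"),
               cdr3nt = NA_character_, d = cl$d_name[i[1L]],
               count = sum(cl$n_molecules[i]),
               v_mutations = sum(cl$n_shm[i] * cl$n_molecules[i]),
               v_aligned_length = sum(cl$v_part_len[i] * cl$n_molecules[i]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$count, df$v, df$j, df$cdr3aa), , drop = FALSE]
  df$freq <- df$count / sum(df$count)
  rownames(df) <- NULL
  new_clonotype_table(df, empty_clonotype_df(), sample_id, timepoint,
                      chain, totals = list(input = sum(df$count),
                                           assigned = sum(df$count),
                                           functional_clones = nrow(df)))
}

#' Read paired FASTQ files into a data.frame of read pairs
#' @param r1_path,r2_path FASTQ paths (may be gzipped)
#' @return data.frame with read_id, r1_seq, r1_qual, r2_seq, r2_qual
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  data.frame(read_id = sub(" .*", "", names(r1)),
             r1_seq = as.character(r1),
             r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
             r2_seq = as.character(r2),
             r2_qual = as.character(S4Vectors::mcols(r2)$qualities),
             stringsAsFactors = FALSE)
}
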