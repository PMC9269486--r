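## Isotype assignment, UMI extraction, MIG assembly and consensus calling,
## and paired-read merging.
##
## Reads are tracked through an attrition table so that
## kept + dropped + unassigned + incoherent equals the input count at every
## stage. Note the collapse from reads to consensuses is a collapse, not a
## loss.

#' Assign an isotype from the constant-region signature at the start of R2
#'
#' The unique signature matching the R2 prefix with at most `max_mismatch`
#' substitutions wins; no match, or a tie between two signatures, yields
#' `NA` (unassigned).
#'
#' @param r2_seq character vector of reverse-mate sequences
#' @param signatures named character vector from [isotype_signatures()]
#' @param max_mismatch maximum substitutions tolerated (default 2)
#' @return character vector of isotype labels, `NA` when unassigned
#' @export
assign_isotype <- function(r2_seq, signatures, max_mismatch = 2L) {
  sig_len <- unique(nchar(signatures))
  if (length(sig_len) != 1L) stop("signatures must share one length")
  prefix <- substr(r2_seq, 1L, sig_len)
  d <- vapply(signatures, function(s) hamming_c(prefix, s),
              integer(length(r2_seq)))
  if (length(r2_seq) == 1L) d <- matrix(d, nrow = 1L)
  best <- apply(d, 1L, min)
  n_best <- rowSums(d == best)
  label <- names(signatures)[apply(d, 1L, which.min)]
  label[best > max_mismatch | n_best > 1L] <- NA_character_
  label
}

#' Extract the UMI and trim the forward mate to the insert
#'
#' The forward-mate layout is TSO tail + UMI + insert. The tail is located
#' at the read start allowing at most one mismatch; reads without a
#' recognizable tail are dropped (returned with `NA` umi).
#'
#' @param r1_seq character vector of forward-mate sequences
#' @param tso_tail TSO tail sequence (default [TSO_TAIL])
#' @param umi_len UMI length (default 8)
#' @return data.frame with columns `umi` and `insert` (`NA` when dropped)
#' @export
extract_umi <- function(r1_seq, tso_tail = TSO_TAIL, umi_len = 8L) {
  tl <- nchar(tso_tail)
  d <- hamming_c(substr(r1_seq, 1L, tl), tso_tail)
  ok <- !is.na(d) & d <= 1L
  umi <- ifelse(ok, substr(r1_seq, tl + 1L, tl + umi_len), NA_character_)
  umi[!is.na(umi) & nchar(umi) < umi_len] <- NA_character_
  insert <- ifelse(is.na(umi), NA_character_,
                   substr(r1_seq, tl + umi_len + 1L, nchar(r1_seq)))
  data.frame(umi = umi, insert = insert, stringsAsFactors = FALSE)
}

#' Group tagged reads into molecular identifier groups (MIGs)
#'
#' Reads are grouped by exact match on (isotype class, UMI); groups smaller
#' than `min_size` are dropped and tallied. A histogram of reads per UMI is
#' returned alongside.
#'
#' @param tagged data.frame with at least columns `umi`, `isotype`, and a
#'   sequence column (any extra columns are carried through)
#' @param min_size minimum MIG size (default 3, allowing error correction
#'   while retaining moderately sequenced molecules)
#' @return list with `migs` (data.frame of kept reads plus a `mig_id`
#'   column), `dropped` (count of reads in undersized groups),
#'   `size_histogram` (table of reads-per-UMI group sizes)
#' @export
build_migs <- function(tagged, min_size = 3L) {
  stopifnot(all(c("umi", "isotype") %in% names(tagged)))
  if (any(is.na(tagged$umi))) stop("all reads must carry a UMI")
  key <- paste(tagged$isotype, tagged$umi, sep = ":")
  sizes <- table(key)
  keep_keys <- names(sizes)[sizes >= min_size]
  keep <- key %in% keep_keys
  migs <- tagged[keep, , drop = FALSE]
  migs$mig_id <- key[keep]
  rownames(migs) <- NULL
  list(migs = migs,
       dropped = sum(!keep),
       size_histogram = table(as.integer(sizes)))
}

#' Plurality consensus of a MIG
#'
#' Members are restricted to the modal length; fewer than `ceil(size / 2)`
#' members at the modal length marks the MIG incoherent and it is
#' discarded. Per position the plurality base wins; ties break by summed
#' member quality, then lexicographically.
#'
#' @param members character vector of member sequences
#' @param quals optional per-member quality strings (summed Phred+33 used
#'   as tie-break weight; equal weights when absent)
#' @return list with `consensus` (string or `NA` when incoherent),
#'   `depth` (members used), `incoherent` (logical)
#' @export
mig_consensus <- function(members, quals = NULL) {
  n <- length(members)
  stopifnot(n >= 1L)
  lens <- nchar(members)
  tab <- table(lens)
  modal_len <- as.integer(names(tab)[which.max(tab)])
  at_modal <- lens == modal_len
  if (sum(at_modal) < ceiling(n / 2)) {
    return(list(consensus = NA_character_, depth = 0L, incoherent = TRUE))
  }
  mem <- members[at_modal]
  w <- if (is.null(quals)) rep(1, length(mem)) else {
    vapply(quals[at_modal], function(q) {
      sum(utf8ToInt(q) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
  }
  list(consensus = as.character(consensus_c(mem, w)),
       depth = length(mem), incoherent = FALSE)
}

#' Merge a forward and reverse-oriented mate over their best ungapped overlap
#'
#' The reverse mate must already be supplied in forward orientation
#' (reverse-complemented). The overlap of length at least `min_overlap`
#' maximizing identity is chosen; the pair merges when identity is at least
#' `min_similarity`. Disagreeing overlap positions are resolved in favour
#' of the higher-quality base.
#'
#' @param fwd forward sequence (5' part)
#' @param rev reverse mate, forward-oriented (3' part)
#' @param min_similarity minimum overlap identity (default 0.70)
#' @param min_overlap minimum overlap length in nt (default 20)
#' @param fwd_qual,rev_qual optional quality strings
#' @return list with `merged` (string or `NA`), `overlap`, `identity`
#' @export
merge_pair <- function(fwd, rev, min_similarity = 0.70, min_overlap = 20L,
                       fwd_qual = NULL, rev_qual = NULL) {
  res <- best_overlap_c(fwd, rev, as.integer(min_overlap))
  o <- res[1L]
  if (o == 0L) return(list(merged = NA_character_, overlap = 0L,
                           identity = NA_real_))
  identity <- res[2L] / o
  if (identity < min_similarity) {
    return(list(merged = NA_character_, overlap = o, identity = identity))
  }
  nf <- nchar(fwd)
  head_part <- substr(fwd, 1L, nf - o)
  ov_f <- substr(fwd, nf - o + 1L, nf)
  ov_r <- substr(rev, 1L, o)
  ov <- ov_f
  if (ov_f != ov_r && !is.null(fwd_qual) && !is.null(rev_qual)) {
    qf <- utf8ToInt(substr(fwd_qual, nf - o + 1L, nf))
    qr <- utf8ToInt(substr(rev_qual, 1L, o))
    cf <- strsplit(ov_f, "")[[1L]]
    cr <- strsplit(ov_r, "")[[1L]]
    use_r <- cf != cr & qr > qf
    cf[use_r] <- cr[use_r]
    ov <- paste(cf, collapse = "")
  }
  tail_part <- substr(rev, o + 1L, nchar(rev))
  list(merged = paste0(head_part, ov, tail_part), overlap = o,
       identity = identity)
}

#' Pre-process read pairs into error-corrected consensus sequences
#'
#' Runs the full pre-processing chain: isotype assignment from R2,
#' UMI extraction from R1, per-pair merging of the R1 insert with the
#' reverse-complemented R2 (unmergeable pairs contribute the R1 insert
#' only), MIG assembly at `min_mig_size`, and per-MIG consensus calling.
#'
#' @param pairs data.frame from [read_fastq_pairs()]
#' @param ref a `germline_reference`
#' @param min_mig_size minimum reads per UMI (default 3)
#' @param min_similarity merge identity threshold (default 0.70)
#' @param min_overlap minimum merge overlap (default 20)
#' @param max_mismatch isotype signature mismatch tolerance (default 2)
#' @param umi_len UMI length (default 8)
#' @param tso_tail TSO tail on R1 (default [TSO_TAIL])
#' @return list with `consensus` (data.frame: mig_id, umi, isotype, size,
#'   consensus), `attrition` (named counts), `mig_histogram`,
#'   `unmerged` (count of pairs that fell back to R1-only)
#' @export
preprocess_reads <- function(pairs, ref, min_mig_size = 3L,
                             min_similarity = 0.70, min_overlap = 20L,
                             max_mismatch = 2L, umi_len = 8L,
                             tso_tail = TSO_TAIL) {
  n_raw <- nrow(pairs)
  sig <- isotype_signatures(ref)
  iso <- assign_isotype(pairs$r2_seq, sig, max_mismatch)
  n_unassigned <- sum(is.na(iso))
  keep <- !is.na(iso)
  pairs <- pairs[keep, , drop = FALSE]
  iso <- iso[keep]
  um <- extract_umi(pairs$r1_seq, tso_tail, umi_len)
  n_no_umi <- sum(is.na(um$umi))
  keep <- !is.na(um$umi)
  pairs <- pairs[keep, , drop = FALSE]
  iso <- iso[keep]
  um <- um[keep, , drop = FALSE]

  ## merge each pair: R1 insert (5') with reverse-complemented R2 (3')
  rev_fwd <- revcomp(pairs$r2_seq)
  tl <- nchar(tso_tail) + umi_len
  merged <- character(nrow(pairs))
  n_unmerged <- 0L
  for (i in seq_len(nrow(pairs))) {
    m <- merge_pair(um$insert[i], rev_fwd[i], min_similarity, min_overlap,
                    fwd_qual = substr(pairs$r1_qual[i], tl + 1L,
                                      nchar(pairs$r1_qual[i])),
                    rev_qual = paste(rev(strsplit(pairs$r2_qual[i],
                                                  "")[[1L]]), collapse = ""))
    if (is.na(m$merged)) {
      merged[i] <- um$insert[i]
      n_unmerged <- n_unmerged + 1L
    } else {
      merged[i] <- m$merged
    }
  }
  tagged <- data.frame(umi = um$umi, isotype = iso, seq = merged,
                       stringsAsFactors = FALSE)
  bm <- build_migs(tagged, min_mig_size)
  n_dropped <- bm$dropped
  cons <- consensus_by_mig(bm$migs)
  n_incoherent_reads <- sum(cons$size[cons$incoherent])
  consensus <- cons[!cons$incoherent,
                    c("mig_id", "umi", "isotype", "size", "consensus")]
  rownames(consensus) <- NULL
  attrition <- c(raw_reads = n_raw,
                 isotype_assigned = n_raw - n_unassigned,
                 umi_extracted = n_raw - n_unassigned - n_no_umi,
                 reads_in_kept_migs = nrow(bm$migs),
                 reads_in_coherent_migs = nrow(bm$migs) - n_incoherent_reads,
                 consensus_count = nrow(consensus))
  list(consensus = consensus, attrition = attrition,
       mig_histogram = bm$size_histogram, unmerged = n_unmerged,
       unassigned = n_unassigned, no_umi = n_no_umi,
       dropped_small_mig = n_dropped,
       incoherent_reads = n_incoherent_reads)
}

consensus_by_mig <- function(migs) {
  split_idx <- split(seq_len(nrow(migs)), migs$mig_id)
  rows <- lapply(names(split_idx), function(k) {
    idx <- split_idx[[k]]
    cc <- mig_consensus(migs$seq[idx])
    data.frame(mig_id = k, umi = migs$umi[idx[1L]],
               isotype = migs$isotype[idx[1L]], size = length(idx),
               consensus = cc$consensus, incoherent = cc$incoherent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
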