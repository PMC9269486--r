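## V/(D)/J annotation: local alignment against germline genes, CDR3
## extraction through the reference anchor coordinates, functionality
## classification, and V-region mutation counting.
##
## Anchors are projected from the annotation table through the alignment;
## they are never rediscovered by motif search. All intervals returned are
## 0-based half-open.

#' Alignment scoring parameters
#'
#' @param match match score (default 2)
#' @param mismatch mismatch score (default -3)
#' @param gap_open gap opening cost (default 6, charged once per gap)
#' @param gap_extend gap extension cost per gapped position (default 1)
#' @param score_floor_frac hits scoring below
#'   `score_floor_frac * match * min(len(seq), len(gene))` are rejected
#' @return list of class `align_params`
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 6,
                         gap_extend = 1, score_floor_frac = 0.4) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 score_floor_frac = score_floor_frac),
            class = "align_params")
}

substitution_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = TRUE)
}

## Local alignment of a vector of query sequences against one gene.
## Returns a data.frame with score/intervals/mismatches plus the aligned
## strings needed for anchor projection.
align_to_gene <- function(seqs, gene_seq, params) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(gene_seq),
    type = "local", substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  data.frame(score = Biostrings::score(al),
             q_start = BiocGenerics::start(pat) - 1L,
             q_end = BiocGenerics::end(pat),
             s_start = BiocGenerics::start(sub) - 1L,
             s_end = BiocGenerics::end(sub),
             mismatches = Biostrings::nmismatch(al),
             aligned_pattern = as.character(Biostrings::alignedPattern(al)),
             aligned_subject = as.character(Biostrings::alignedSubject(al)),
             stringsAsFactors = FALSE)
}

#' Align sequences against all candidate genes of one segment type
#'
#' Every candidate is scored by local alignment; the highest score wins,
#' ties break by fewer mismatches, then by locus order of the gene name
#' (the order of `candidates`). Hits scoring below the configured floor
#' are reported as missing (`NA` gene). Scores are computed for every
#' candidate; the full alignment (intervals, mismatches, aligned strings)
#' is materialized only for the winning gene.
#'
#' @param seqs character vector of query sequences
#' @param candidates data.frame of gene records (one segment type), in
#'   locus order
#' @param params an [align_params()]
#' @return data.frame with one row per query: `gene`, `score`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (0-based half-open), `mismatches`,
#'   `aligned_length`, and the aligned strings used for projection
#' @export
align_segment <- function(seqs, candidates, params = align_params()) {
  stopifnot(nrow(candidates) >= 1L)
  if (any(nchar(seqs) == 0L)) stop("empty query sequence")
  n <- length(seqs)
  ng <- nrow(candidates)
  qset <- Biostrings::DNAStringSet(seqs)
  mat <- substitution_matrix(params)
  scores <- matrix(NA_real_, nrow = n, ncol = ng)
  for (k in seq_len(ng)) {
    scores[, k] <- Biostrings::pairwiseAlignment(
      qset, Biostrings::DNAString(candidates$sequence[k]),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
  }
  top <- apply(scores, 1L, max)
  winner <- integer(n)
  for (i in seq_len(n)) {
    tied <- which(scores[i, ] == top[i])
    if (length(tied) == 1L) {
      winner[i] <- tied
    } else {
      ## break score ties by fewer mismatches, then locus order
      mm <- vapply(tied, function(k) {
        align_to_gene(seqs[i], candidates$sequence[k], params)$mismatches
      }, numeric(1))
      winner[i] <- tied[which.min(mm)]
    }
  }
  best <- vector("list", n)
  for (k in unique(winner)) {
    rows <- which(winner == k)
    cur <- align_to_gene(seqs[rows], candidates$sequence[k], params)
    cur$gene <- candidates$name[k]
    cur$gene_len <- nchar(candidates$sequence[k])
    for (r in seq_along(rows)) best[[rows[r]]] <- cur[r, , drop = FALSE]
  }
  best <- do.call(rbind, best)
  floor_score <- params$score_floor_frac * params$match *
    pmin(nchar(seqs), best$gene_len)
  below <- best$score < floor_score
  best$gene[below] <- NA_character_
  best$aligned_length <- nchar(best$aligned_pattern)
  rownames(best) <- NULL
  best[, c("gene", "score", "q_start", "q_end", "s_start", "s_end",
           "mismatches", "aligned_length", "aligned_pattern",
           "aligned_subject")]
}

## Project a 0-based gene offset through an alignment row onto the query.
## Returns the 0-based query offset, or NA when the position falls outside
## the alignment or lands on a deletion.
project_position <- function(hit, ref_pos0) {
  if (ref_pos0 < hit$s_start || ref_pos0 >= hit$s_end) return(NA_integer_)
  pa <- strsplit(hit$aligned_pattern, "")[[1L]]
  sa <- strsplit(hit$aligned_subject, "")[[1L]]
  q <- hit$q_start
  s <- hit$s_start
  for (i in seq_along(pa)) {
    if (sa[i] != "-" && s == ref_pos0) {
      if (pa[i] == "-") return(NA_integer_)
      return(q)
    }
    if (pa[i] != "-") q <- q + 1L
    if (sa[i] != "-") s <- s + 1L
  }
  NA_integer_
}

#' Find the best D gene match in the inter-V-J region
#'
#' The best ungapped exact match of any D-gene substring of at least
#' `min_match` nt wins; shorter or absent matches return `NA` (the
#' "D not identified" class). Ties break by locus order.
#'
#' @param inter_vj nucleotide sequence between the V and J alignments
#' @param d_genes data.frame of D gene records in locus order
#' @param min_match minimum exact match length (default 5)
#' @return list with `gene` (or `NA`) and `length` of the match
#' @export
find_d <- function(inter_vj, d_genes, min_match = 5L) {
  best_gene <- NA_character_
  best_len <- 0L
  n <- nchar(inter_vj)
  if (n >= min_match) {
    for (k in seq_len(nrow(d_genes))) {
      len <- longest_common_substring(inter_vj, d_genes$sequence[k])
      if (len > best_len) {
        best_len <- len
        best_gene <- d_genes$name[k]
      }
    }
  }
  if (best_len < min_match) {
    return(list(gene = NA_character_, length = best_len))
  }
  list(gene = best_gene, length = best_len)
}

longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(bv == av[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

#' Extract the anchored CDR3 from V and J alignments
#'
#' The Cys104 codon start is projected through the V alignment and the
#' Trp/Phe118 codon through the J alignment. The anchored CDR3 runs from
#' Cys104 through the anchor codon inclusive; the short CDR3 (IMGT
#' 105-117) drops both anchors. When the projected region begins X-C (a
#' leading residue before the conserved cysteine, as arises from off-by-one
#' anchor annotations on some loci), the leading residue is trimmed so the
#' anchored CDR3 always begins with C; the rule self-disables on correct
#' anchors.
#'
#' @param seq query sequence
#' @param v_hit,j_hit one-row hit data.frames from [align_segment()]
#' @param v_anchor,j_anchor 0-based anchor offsets of the winning genes
#' @return list with `cdr3_nt`, `cdr3_aa` (anchored translation),
#'   `cdr3_aa_short`, `frame_ok`, `q_cys`, `q_anchor_end`, or NULL when an
#'   anchor cannot be projected
#' @export
extract_cdr3 <- function(seq, v_hit, j_hit, v_anchor, j_anchor) {
  q_cys <- project_position(v_hit, v_anchor)
  q_anchor <- project_position(j_hit, j_anchor)
  if (is.na(q_cys) || is.na(q_anchor)) return(NULL)
  if (q_anchor + 3L > nchar(seq) || q_anchor <= q_cys) return(NULL)
  cdr3_nt <- substr(seq, q_cys + 1L, q_anchor + 3L)
  frame_ok <- nchar(cdr3_nt) %% 3L == 0L
  cdr3_aa <- if (frame_ok) translate_nt(cdr3_nt) else NA_character_
  ## leading-X-before-Cys correction
  if (frame_ok && !is.na(cdr3_aa) && nchar(cdr3_aa) >= 2L &&
      substr(cdr3_aa, 1L, 1L) != "C" && substr(cdr3_aa, 2L, 2L) == "C") {
    q_cys <- q_cys + 3L
    cdr3_nt <- substr(seq, q_cys + 1L, q_anchor + 3L)
    cdr3_aa <- translate_nt(cdr3_nt)
  }
  short <- if (frame_ok && nchar(cdr3_aa) >= 2L) {
    substr(cdr3_aa, 2L, nchar(cdr3_aa) - 1L)
  } else NA_character_
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, cdr3_aa_short = short,
       frame_ok = frame_ok, q_cys = q_cys, q_anchor_end = q_anchor + 3L)
}

#' Classify functionality of an annotated sequence
#'
#' Functional means the anchored CDR3 is in frame and the translated
#' region, in the cysteine's reading frame from the start of the V
#' alignment through the end of the J alignment, contains no stop codon.
#'
#' @param seq query sequence
#' @param frame_ok CDR3 frame flag from [extract_cdr3()]
#' @param q_cys 0-based query offset of the Cys codon
#' @param q_v_start 0-based query start of the V alignment
#' @param q_j_end 0-based query end (exclusive) of the J alignment
#' @return list with `functional` and `has_stop`
#' @export
classify_functionality <- function(seq, frame_ok, q_cys, q_v_start,
                                   q_j_end) {
  if (!frame_ok) return(list(functional = FALSE, has_stop = NA))
  start0 <- q_v_start + (q_cys - q_v_start) %% 3L
  aa <- translate_nt(substr(seq, start0 + 1L, q_j_end))
  has_stop <- grepl("*", aa, fixed = TRUE)
  list(functional = !has_stop, has_stop = has_stop)
}

#' Count mutations within the V alignment
#'
#' Substitutions within the aligned V interval plus one mutation per gapped
#' alignment column.
#'
#' @param v_hit one-row hit data.frame from [align_segment()]
#' @return list with `v_mutations` and `v_aligned_length`
#' @export
count_v_mutations <- function(v_hit) {
  gaps <- sum(strsplit(v_hit$aligned_pattern, "")[[1L]] == "-") +
    sum(strsplit(v_hit$aligned_subject, "")[[1L]] == "-")
  list(v_mutations = v_hit$mismatches + gaps,
       v_aligned_length = nchar(v_hit$aligned_pattern))
}

#' Annotate error-corrected consensus sequences
#'
#' Aligns each consensus against the germline V and J genes of its chain
#' (top hit retained), identifies the D gene in the inter-V-J region for
#' IGH, extracts the CDR3 through the anchor coordinates, classifies
#' functionality, and counts V-region mutations. Sequences without both a
#' V and J hit and a CDR3 are dropped and tallied.
#'
#' @param consensus data.frame with columns `umi`, `isotype`, `size`,
#'   `consensus` (from [preprocess_reads()])
#' @param ref a `germline_reference`
#' @param params an [align_params()]
#' @param d_min_match minimum D match length (default 5)
#' @return list with `annotations` (one row per retained consensus) and
#'   `log` (counts: input, aligned, with_cdr3 per chain)
#' @export
annotate_consensus <- function(consensus, ref, params = align_params(),
                               d_min_match = 5L) {
  consensus$chain <- isotype_chain(consensus$isotype)
  out <- list()
  logs <- list()
  for (ch in unique(consensus$chain)) {
    idx <- which(consensus$chain == ch)
    seqs <- consensus$consensus[idx]
    uq <- unique(seqs)
    map <- match(seqs, uq)
    vs <- get_genes(ref, ch, "V")
    js <- get_genes(ref, ch, "J")
    ds <- if (ch == "IGH") get_genes(ref, ch, "D") else NULL
    vh <- align_segment(uq, vs, params)
    jh <- align_segment(uq, js, params)
    ann_uq <- vector("list", length(uq))
    for (u in seq_along(uq)) {
      v <- vh[u, ]; j <- jh[u, ]
      if (is.na(v$gene) || is.na(j$gene)) next
      if (j$q_start < v$q_end - 6L) next  # J must lie downstream of V
      v_anchor <- gene_by_name(ref, v$gene)$anchor_offset
      j_anchor <- gene_by_name(ref, j$gene)$anchor_offset
      cdr3 <- extract_cdr3(uq[u], v, j, v_anchor, j_anchor)
      if (is.null(cdr3)) next
      fn <- classify_functionality(uq[u], cdr3$frame_ok, cdr3$q_cys,
                                   v$q_start, j$q_end)
      mut <- count_v_mutations(v)
      d_gene <- NA_character_
      if (!is.null(ds) && nrow(ds) > 0L && j$q_start > v$q_end) {
        inter <- substr(uq[u], v$q_end + 1L, j$q_start)
        d_gene <- find_d(inter, ds, d_min_match)$gene
      }
      ann_uq[[u]] <- data.frame(
        chain = ch, v_gene = v$gene, d_gene = d_gene, j_gene = j$gene,
        v_score = v$score, j_score = j$score,
        cdr3_nt = cdr3$cdr3_nt, cdr3_aa = cdr3$cdr3_aa,
        cdr3_aa_short = cdr3$cdr3_aa_short,
        frame_ok = cdr3$frame_ok, has_stop = isTRUE(fn$has_stop),
        functional = fn$functional,
        v_mutations = mut$v_mutations,
        v_aligned_length = mut$v_aligned_length,
        stringsAsFactors = FALSE)
    }
    kept_uq <- !vapply(ann_uq, is.null, logical(1))
    aligned_uq <- !is.na(vh$gene) & !is.na(jh$gene)
    rows <- which(kept_uq[map])
    if (length(rows)) {
      ann <- do.call(rbind, ann_uq[map[rows]])
      ann <- cbind(consensus[idx[rows],
                             c("umi", "isotype", "size"), drop = FALSE],
                   ann)
      rownames(ann) <- NULL
      out[[ch]] <- ann
    }
    logs[[ch]] <- data.frame(chain = ch, input = length(idx),
                             aligned = sum(aligned_uq[map]),
                             with_cdr3 = length(rows),
                             stringsAsFactors = FALSE)
  }
  list(annotations = if (length(out)) do.call(rbind, out) else NULL,
       log = do.call(rbind, logs))
}
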