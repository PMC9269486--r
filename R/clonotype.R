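## Clonotype assembly, QC filtering, and clonotype-table IO.
##
## A clonotype is the triple (V gene, J gene, short CDR3 amino-acid
## sequence). The short (IMGT 105-117) CDR3 is the key; the anchored form
## is stored alongside. Non-functional clonotypes are kept in a parallel
## partition. Heavy-chain isotypes (IGM/IGG/IGA/IGE) are concatenated into
## a single IGH table.

#' Assemble annotated sequences into a clonotype table
#'
#' One clonotype per (v_gene, j_gene, cdr3_aa_short); counts are the number
#' of supporting consensus sequences and frequencies are computed within
#' the functional partition. The modal D gene is reported for information
#' only and is never part of the key.
#'
#' @param annotations data.frame from [annotate_consensus()]
#' @param sample_id sample label
#' @param timepoint time-point label (e.g. "T1")
#' @param chain chain label; rows of other chains are ignored
#' @return object of class `clonotype_table`: list with `sample_id`,
#'   `timepoint`, `chain`, `clonotypes` (functional, sorted by descending
#'   count), `nonfunctional`, and `totals`
#' @export
assemble_clonotypes <- function(annotations, sample_id, timepoint, chain) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    warning("no annotated sequences for ", sample_id, " ", chain)
    return(new_clonotype_table(empty_clonotype_df(), empty_clonotype_df(),
                               sample_id, timepoint, chain,
                               totals = list(input = 0L, assigned = 0L,
                                             functional_clones = 0L)))
  }
  ann <- annotations[annotations$chain == chain &
                       !is.na(annotations$cdr3_aa_short), , drop = FALSE]
  collapse <- function(df) {
    if (nrow(df) == 0L) return(empty_clonotype_df())
    key <- paste(df$v_gene, df$j_gene, df$cdr3_aa_short, sep = "|")
    idx <- split(seq_len(nrow(df)), key)
    rows <- lapply(idx, function(i) {
      d_tab <- table(df$d_gene[i], useNA = "no")
      data.frame(v = df$v_gene[i[1L]], j = df$j_gene[i[1L]],
                 cdr3aa = df$cdr3_aa_short[i[1L]],
                 cdr3aa_anchored = df$cdr3_aa[i[1L]],
                 cdr3nt = df$cdr3_nt[i[1L]],
                 d = if (length(d_tab)) names(d_tab)[which.max(d_tab)]
                     else NA_character_,
                 count = length(i),
                 v_mutations = sum(df$v_mutations[i]),
                 v_aligned_length = sum(df$v_aligned_length[i]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$count, out$v, out$j, out$cdr3aa), , drop = FALSE]
    out$freq <- out$count / sum(out$count)
    rownames(out) <- NULL
    out
  }
  func <- collapse(ann[ann$functional, , drop = FALSE])
  nonf <- collapse(ann[!ann$functional, , drop = FALSE])
  new_clonotype_table(func, nonf, sample_id, timepoint, chain,
                      totals = list(input = nrow(annotations),
                                    assigned = nrow(ann),
                                    functional_clones = nrow(func)))
}

empty_clonotype_df <- function() {
  data.frame(v = character(0), j = character(0), cdr3aa = character(0),
             cdr3aa_anchored = character(0), cdr3nt = character(0),
             d = character(0), count = integer(0),
             v_mutations = integer(0), v_aligned_length = integer(0),
             freq = numeric(0), stringsAsFactors = FALSE)
}

new_clonotype_table <- function(clonotypes, nonfunctional, sample_id,
                                timepoint, chain, totals) {
  structure(list(sample_id = sample_id, timepoint = timepoint,
                 chain = chain, clonotypes = clonotypes,
                 nonfunctional = nonfunctional, totals = totals),
            class = "clonotype_table")
}

#' Construct a clonotype table directly from counts
#'
#' Convenience constructor for worked examples and fixtures: builds a valid
#' `clonotype_table` from vectors of V/J genes, CDR3s and counts.
#'
#' @param v,j,cdr3aa,count equal-length vectors (recycled where sensible)
#' @param d optional D gene labels
#' @param sample_id,timepoint,chain table labels
#' @param v_mutations,v_aligned_length optional per-clonotype mutation data
#' @return a `clonotype_table`
#' @export
clonotype_table <- function(v, j, cdr3aa, count, d = NA_character_,
                            sample_id = "S1", timepoint = "T1",
                            chain = "IGH", v_mutations = 0L,
                            v_aligned_length = 300L) {
  n <- max(length(v), length(j), length(cdr3aa), length(count))
  df <- data.frame(v = rep_len(v, n), j = rep_len(j, n),
                   cdr3aa = rep_len(cdr3aa, n),
                   cdr3aa_anchored = paste0("C", rep_len(cdr3aa, n), "W"),
                   cdr3nt = NA_character_,
                   d = rep_len(d, n), count = as.integer(rep_len(count, n)),
                   v_mutations = as.integer(rep_len(v_mutations, n)),
                   v_aligned_length = as.integer(rep_len(v_aligned_length, n)),
                   stringsAsFactors = FALSE)
  key <- paste(df$v, df$j, df$cdr3aa)
  if (anyDuplicated(key)) stop("duplicate clonotype keys")
  df <- df[order(-df$count, df$v, df$j, df$cdr3aa), , drop = FALSE]
  df$freq <- df$count / sum(df$count)
  rownames(df) <- NULL
  new_clonotype_table(df, empty_clonotype_df(), sample_id, timepoint,
                      chain, totals = list(input = sum(df$count),
                                           assigned = sum(df$count),
                                           functional_clones = nrow(df)))
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table %s %s %s: %d functional clonotypes (%d reads), %d non-functional\n",
              x$sample_id, x$timepoint, x$chain, nrow(x$clonotypes),
              sum(x$clonotypes$count), nrow(x$nonfunctional)))
  invisible(x)
}

#' Quality-control filter for sample-timepoint-chain datasets
#'
#' A dataset is excluded when it has fewer than `min_reads` error-corrected
#' reads ("less than 1,000" excludes 999 and keeps 1000) or when more than
#' `max_unassigned_pct` percent of reads failed to define clonotypes
#' (exactly 95.0 is kept).
#'
#' @param stats data.frame with columns `sample_id`, `timepoint`, `chain`,
#'   `reads`, `pct_unassigned`
#' @param min_reads read-count threshold (default 1000)
#' @param max_unassigned_pct unassigned-percent threshold (default 95)
#' @return the input with `include` (logical) and `reason` columns
#' @export
qc_filter <- function(stats, min_reads = 1000L, max_unassigned_pct = 95) {
  low <- stats$reads < min_reads
  high <- stats$pct_unassigned > max_unassigned_pct
  stats$include <- !(low | high)
  stats$reason <- ""
  stats$reason[low] <- sprintf("reads < %d", min_reads)
  stats$reason[high & !low] <- sprintf("pct_unassigned > %s",
                                       format(max_unassigned_pct))
  stats$reason[high & low] <- sprintf("reads < %d; pct_unassigned > %s",
                                      min_reads,
                                      format(max_unassigned_pct))
  stats
}

CLONOTYPE_COLUMNS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")

#' Write a clonotype table to TSV
#'
#' Column layout: `count freq cdr3nt cdr3aa v d j`. The write-read-write
#' cycle is byte-identical.
#'
#' @param table a `clonotype_table`
#' @param path output path
#' @param partition "functional" (default) or "nonfunctional"
#' @return the path, invisibly
#' @export
write_clonotype_table <- function(table, path, partition = "functional") {
  df <- if (partition == "functional") table$clonotypes else table$nonfunctional
  out <- data.frame(count = df$count,
                    freq = format_freq(df$freq),
                    cdr3nt = ifelse(is.na(df$cdr3nt), ".", df$cdr3nt),
                    cdr3aa = df$cdr3aa,
                    v = df$v,
                    d = ifelse(is.na(df$d), ".", df$d),
                    j = df$j, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_freq <- function(x) formatC(x, digits = 12, format = "g")

#' Read a clonotype table from TSV
#'
#' Columns must appear exactly in the order `count freq cdr3nt cdr3aa v d
#' j`; the frequency column is recomputed from the counts and must agree
#' within 1e-9.
#'
#' @param path TSV path
#' @param sample_id,timepoint,chain labels for the resulting table
#' @return a `clonotype_table`
#' @export
read_clonotype_table <- function(path, sample_id = "S1", timepoint = "T1",
                                 chain = "IGH") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(count = "integer",
                                         freq = "numeric",
                                         cdr3nt = "character",
                                         cdr3aa = "character",
                                         v = "character", d = "character",
                                         j = "character"))
  if (!identical(names(df), CLONOTYPE_COLUMNS)) {
    bad <- setdiff(union(names(df), CLONOTYPE_COLUMNS),
                   intersect(names(df), CLONOTYPE_COLUMNS))
    if (length(bad) == 0L) bad <- names(df)[names(df) != CLONOTYPE_COLUMNS]
    stop("unexpected clonotype table columns: ",
         paste(bad, collapse = ", "))
  }
  recomputed <- df$count / sum(df$count)
  if (any(abs(recomputed - df$freq) > 1e-9)) {
    stop("freq column inconsistent with counts in ", path)
  }
  out <- data.frame(v = df$v, j = df$j, cdr3aa = df$cdr3aa,
                    cdr3aa_anchored = NA_character_,
                    cdr3nt = ifelse(df$cdr3nt == ".", NA_character_,
                                    df$cdr3nt),
                    d = ifelse(df$d == ".", NA_character_, df$d),
                    count = df$count, v_mutations = NA_integer_,
                    v_aligned_length = NA_integer_, freq = recomputed,
                    stringsAsFactors = FALSE)
  new_clonotype_table(out, empty_clonotype_df(), sample_id, timepoint,
                      chain, totals = list(input = sum(out$count),
                                           assigned = sum(out$count),
                                           functional_clones = nrow(out)))
}
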