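## Pairwise repertoire overlap across time points.

#' Overlap between two clonotype tables
#'
#' Clonotypes match on the exact (V gene, J gene, short CDR3 amino-acid
#' sequence) key; clonotypes sharing a CDR3 but differing in V or J do not
#' overlap. Reports shared clonotypes with their frequencies in both
#' tables, the Jaccard index over clonotype keys, the proportion of each
#' table's keys that are shared, and a least-squares regression of the
#' shared clonotypes' log10 frequencies (table B on table A), fitted only
#' when at least three clonotypes are shared.
#'
#' @param table_a,table_b `clonotype_table`s of the same chain
#' @param log10_freq regress on log10 frequencies (default TRUE; linear
#'   space otherwise)
#' @return list of class `overlap_result`: `shared` (data.frame key,
#'   freq_a, freq_b), `jaccard`, `proportion_shared_a`,
#'   `proportion_shared_b`, `regression` (slope, intercept, r_squared;
#'   `NULL` when fewer than three shared clonotypes)
#' @export
overlap_pair <- function(table_a, table_b, log10_freq = TRUE) {
  if (!identical(table_a$chain, table_b$chain)) {
    stop("tables must be of the same chain (got ", table_a$chain, " vs ",
         table_b$chain, ")")
  }
  a <- table_a$clonotypes
  b <- table_b$clonotypes
  key_a <- paste(a$v, a$j, a$cdr3aa, sep = "|")
  key_b <- paste(b$v, b$j, b$cdr3aa, sep = "|")
  shared_keys <- intersect(key_a, key_b)
  n_union <- length(union(key_a, key_b))
  shared <- data.frame(
    key = shared_keys,
    freq_a = a$freq[match(shared_keys, key_a)],
    freq_b = b$freq[match(shared_keys, key_b)],
    stringsAsFactors = FALSE)
  regression <- NULL
  if (nrow(shared) >= 3L) {
    xs <- if (log10_freq) log10(shared$freq_a) else shared$freq_a
    ys <- if (log10_freq) log10(shared$freq_b) else shared$freq_b
    sxx <- sum((xs - mean(xs))^2)
    if (sxx > 0) {
      sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
      syy <- sum((ys - mean(ys))^2)
      slope <- sxy / sxx
      regression <- list(slope = slope,
                         intercept = mean(ys) - slope * mean(xs),
                         r_squared = if (syy == 0) 1 else sxy^2 / (sxx * syy))
    }
  }
  structure(list(shared = shared,
                 jaccard = if (n_union == 0L) 0 else
                   length(shared_keys) / n_union,
                 proportion_shared_a = if (length(key_a)) {
                   length(shared_keys) / length(key_a)
                 } else 0,
                 proportion_shared_b = if (length(key_b)) {
                   length(shared_keys) / length(key_b)
                 } else 0,
                 regression = regression),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d shared clonotypes, Jaccard %.4f\n",
              nrow(x$shared), x$jaccard))
  if (!is.null(x$regression)) {
    cat(sprintf("  log-frequency regression: slope %.3f, R^2 %.3f\n",
                x$regression$slope, x$regression$r_squared))
  }
  invisible(x)
}
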