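## Repertoire statistics: segment usage, VJ pairing, spectratypes,
## top-clone fractions, per-position CDR3 composition, sequence-logo
## information content, biochemical class profiles, and usage correlation.
##
## All proportion outputs sum to 1 before any reporting filter is applied.

clonotype_df <- function(table) {
  if (inherits(table, "clonotype_table")) table$clonotypes else table
}

#' Gene segment usage proportions for one clonotype table
#'
#' Weighted usage weights each clonotype by its count; unweighted counts
#' each clonotype once. Unassigned D genes are reported as their own
#' `"unassigned"` category.
#'
#' @param table a `clonotype_table` (or its functional data.frame)
#' @param segment "V", "D" or "J"
#' @param weighted weight by clone counts (default TRUE)
#' @param by_family aggregate genes into families (prefix before "-")
#' @return data.frame with `gene` and `proportion` (sums to 1)
#' @export
segment_usage <- function(table, segment = "V", weighted = TRUE,
                          by_family = FALSE) {
  df <- clonotype_df(table)
  gene <- switch(segment, V = df$v, D = df$d, J = df$j,
                 stop("segment must be V, D or J"))
  if (segment == "D") gene[is.na(gene)] <- "unassigned"
  if (by_family) {
    fam <- sub("-.*$", "", gene)
    fam[gene == "unassigned"] <- "unassigned"
    gene <- fam
  }
  w <- if (weighted) df$count else rep(1, nrow(df))
  agg <- tapply(w, gene, sum)
  out <- data.frame(gene = names(agg),
                    proportion = as.numeric(agg) / sum(w),
                    stringsAsFactors = FALSE)
  out[order(-out$proportion, out$gene), , drop = FALSE]
}

#' Usage matrix across samples
#'
#' @param tables list of `clonotype_table`s
#' @param segment,weighted,by_family passed to [segment_usage()]
#' @return samples x genes matrix of proportions (0 for absent genes)
#' @export
usage_matrix <- function(tables, segment = "V", weighted = TRUE,
                         by_family = FALSE) {
  profs <- lapply(tables, segment_usage, segment = segment,
                  weighted = weighted, by_family = by_family)
  genes <- sort(unique(unlist(lapply(profs, `[[`, "gene"))))
  m <- t(vapply(profs, function(p) {
    v <- stats::setNames(rep(0, length(genes)), genes)
    v[p$gene] <- p$proportion
    v
  }, numeric(length(genes))))
  rownames(m) <- vapply(tables, function(t) {
    paste(t$sample_id, t$timepoint, sep = "_")
  }, character(1))
  m
}

#' Z-score usage clustering across samples
#'
#' Gene proportions are Z-scored across samples (a zero-variance gene maps
#' to all-zero scores), then clustered by Euclidean distance with complete
#' linkage. Leaf order is deterministic.
#'
#' @param usage samples x genes matrix from [usage_matrix()]
#' @return list with `z` (Z-scored matrix), `dist`, `hclust`, `order`
#' @export
usage_cluster <- function(usage) {
  z <- apply(usage, 2L, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(usage),
                                   dimnames = dimnames(usage))
  rownames(z) <- rownames(usage)
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = "complete")
  list(z = z, dist = d, hclust = hc, order = hc$order)
}

#' VJ pairing fractions across tables
#'
#' Fractions are computed over all pairs before filtering; the
#' `min_fraction` filter (strictly greater than) applies to the reported
#' subset only.
#'
#' @param tables list of `clonotype_table`s (or a single table)
#' @param weighted weight by clone counts (default FALSE: each clonotype
#'   counts once)
#' @param min_fraction reporting filter, strictly greater than
#'   (default 0.01)
#' @return data.frame `v`, `j`, `fraction` (reported subset); the full
#'   unfiltered pairing table is attached as attribute `"full"`
#' @export
vj_pairing <- function(tables, weighted = FALSE, min_fraction = 0.01) {
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  dfs <- lapply(tables, clonotype_df)
  df <- do.call(rbind, dfs)
  w <- if (weighted) df$count else rep(1, nrow(df))
  agg <- tapply(w, paste(df$v, df$j, sep = "\t"), sum)
  parts <- do.call(rbind, strsplit(names(agg), "\t", fixed = TRUE))
  full <- data.frame(v = parts[, 1L], j = parts[, 2L],
                     fraction = as.numeric(agg) / sum(w),
                     stringsAsFactors = FALSE)
  full <- full[order(-full$fraction, full$v, full$j), , drop = FALSE]
  rownames(full) <- NULL
  out <- full[full$fraction > min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Spectratype: mean proportion of functional clones per CDR3 length
#'
#' Each sample contributes its clone-frequency-weighted CDR3 length
#' distribution with equal sample weight; lengths with mean proportion
#' below `min_mean` are excluded.
#'
#' @param tables list of `clonotype_table`s
#' @param min_mean exclusion threshold (default 1e-5)
#' @return data.frame `length`, `mean_proportion`
#' @export
spectratype <- function(tables, min_mean = 1e-5) {
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  per_sample <- lapply(tables, function(t) {
    df <- clonotype_df(t)
    len <- nchar(df$cdr3aa)
    agg <- tapply(df$freq, len, sum)
    data.frame(length = as.integer(names(agg)),
               proportion = as.numeric(agg))
  })
  lengths <- sort(unique(unlist(lapply(per_sample, `[[`, "length"))))
  m <- vapply(per_sample, function(p) {
    v <- stats::setNames(rep(0, length(lengths)), lengths)
    v[as.character(p$length)] <- p$proportion
    v
  }, numeric(length(lengths)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(lengths))
  mean_prop <- rowMeans(m)
  out <- data.frame(length = lengths, mean_proportion = mean_prop)
  out[out$mean_proportion >= min_mean, , drop = FALSE]
}

#' Rank CDR3 sequences by pooled fraction across samples
#'
#' Sequences are grouped by CDR3 amino-acid sequence; `n_samples` counts
#' clonotype occurrences across tables (the same CDR3 with different V/J
#' genes counts separately), `total_count` sums supporting reads, and the
#' pooled fraction is total_count over all reads in the included tables.
#' Alternatively a data.frame with a precomputed `fraction` column (and
#' optionally `sequence`/`chain`) can be supplied and is ranked as-is.
#'
#' @param tables list of `clonotype_table`s, or a data.frame with a
#'   `fraction` column
#' @param n report the cumulative fraction of the top `n` sequences
#' @return data.frame ranked by fraction with attribute `"cumulative"`,
#'   the summed fraction of the top `n`
#' @export
top_clone_fractions <- function(tables, n = 3L) {
  if (is.data.frame(tables) && "fraction" %in% names(tables)) {
    out <- tables[order(-tables$fraction), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "cumulative") <- sum(out$fraction[seq_len(min(n, nrow(out)))])
    return(out)
  }
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  dfs <- lapply(tables, clonotype_df)
  all_counts <- sum(vapply(dfs, function(d) sum(d$count), numeric(1)))
  df <- do.call(rbind, dfs)
  idx <- split(seq_len(nrow(df)), df$cdr3aa)
  out <- do.call(rbind, lapply(names(idx), function(s) {
    i <- idx[[s]]
    data.frame(sequence = s, n_samples = length(i),
               total_count = sum(df$count[i]),
               fraction = sum(df$count[i]) / all_counts,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$fraction, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cumulative") <- sum(out$fraction[seq_len(min(n, nrow(out)))])
  out
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Per-position amino-acid frequency profile of fixed-length CDR3s
#'
#' Keeps only CDR3s of `target_length` (short form, or anchored form when
#' `include_flanks`), computes count-weighted per-position amino-acid
#' frequencies per sample, and averages across samples with equal weight.
#' Positions are labelled with IMGT numbers (105..117, plus 104 and 118
#' for the flanks).
#'
#' @param tables list of `clonotype_table`s
#' @param chain chain label (tables of other chains are skipped)
#' @param target_length CDR3 length to keep, in amino acids (short form)
#' @param include_flanks include the anchor residues (Cys104 and
#'   Trp/Phe118)
#' @param weighted weight by clone counts within each sample
#' @return matrix 20 x positions, each column summing to 1; class
#'   `position_profile` with attribute `positions` (IMGT labels)
#' @export
position_profile <- function(tables, chain, target_length,
                             include_flanks = FALSE, weighted = TRUE) {
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  tables <- Filter(function(t) t$chain == chain, tables)
  if (!length(tables)) stop("no tables for chain ", chain)
  width <- if (include_flanks) target_length + 2L else target_length
  per_sample <- list()
  for (t in tables) {
    df <- clonotype_df(t)
    seqs <- if (include_flanks) df$cdr3aa_anchored else df$cdr3aa
    keep <- !is.na(seqs) & nchar(seqs) == width
    if (!any(keep)) next
    seqs <- seqs[keep]
    w <- if (weighted) df$count[keep] else rep(1, sum(keep))
    m <- matrix(0, nrow = length(AA_ALPHABET), ncol = width,
                dimnames = list(AA_ALPHABET, NULL))
    chars <- do.call(rbind, strsplit(seqs, ""))
    for (p in seq_len(width)) {
      agg <- tapply(w, chars[, p], sum)
      agg <- agg[names(agg) %in% AA_ALPHABET]
      m[names(agg), p] <- as.numeric(agg)
    }
    per_sample[[length(per_sample) + 1L]] <- sweep(m, 2L, colSums(m), "/")
  }
  if (!length(per_sample)) stop("no CDR3s of length ", target_length)
  prof <- Reduce(`+`, per_sample) / length(per_sample)
  positions <- if (include_flanks) c(104L, 105L:(105L + target_length - 1L), 118L)
               else 105L:(105L + target_length - 1L)
  attr(prof, "positions") <- positions
  colnames(prof) <- positions
  class(prof) <- c("position_profile", class(prof))
  prof
}

#' Sequence-logo letter heights in bits
#'
#' Column information is `R = log2(20) - H(column)` (Shannon entropy, no
#' small-sample correction); each letter's height is its frequency times
#' `R`.
#'
#' @param profile a `position_profile` (20 x positions matrix)
#' @return matrix of the same shape with per-letter bit heights; attribute
#'   `"information"` holds the per-column information content `R`
#' @export
logo_heights <- function(profile) {
  H <- apply(profile, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  R <- log2(length(AA_ALPHABET)) - H
  heights <- sweep(unclass(profile), 2L, R, "*")
  attr(heights, "information") <- R
  heights
}

## IMGT-style amino-acid class tables used for biochemical profiles.
AA_CLASSES <- list(
  hydropathy = c(A = "hydrophobic", C = "hydrophobic", F = "hydrophobic",
                 I = "hydrophobic", L = "hydrophobic", M = "hydrophobic",
                 V = "hydrophobic", W = "hydrophobic",
                 G = "neutral", H = "neutral", P = "neutral",
                 S = "neutral", T = "neutral", Y = "neutral",
                 R = "hydrophilic", N = "hydrophilic", D = "hydrophilic",
                 Q = "hydrophilic", E = "hydrophilic", K = "hydrophilic"),
  size = c(A = "very_small", G = "very_small", S = "very_small",
           C = "small", D = "small", N = "small", P = "small", T = "small",
           E = "medium", H = "medium", Q = "medium", V = "medium",
           I = "large", L = "large", K = "large", M = "large", R = "large",
           F = "very_large", W = "very_large", Y = "very_large"),
  chemical = c(A = "aliphatic", G = "aliphatic", I = "aliphatic",
               L = "aliphatic", P = "aliphatic", V = "aliphatic",
               F = "aromatic", W = "aromatic", Y = "aromatic",
               C = "sulfur", M = "sulfur",
               S = "hydroxyl", T = "hydroxyl",
               R = "basic", H = "basic", K = "basic",
               D = "acidic", E = "acidic",
               N = "amide", Q = "amide"),
  charge = c(R = "positive", H = "positive", K = "positive",
             D = "negative", E = "negative",
             A = "uncharged", C = "uncharged", F = "uncharged",
             G = "uncharged", I = "uncharged", L = "uncharged",
             M = "uncharged", N = "uncharged", P = "uncharged",
             Q = "uncharged", S = "uncharged", T = "uncharged",
             V = "uncharged", W = "uncharged", Y = "uncharged"),
  hydrogen_bond = c(R = "donor", K = "donor", W = "donor",
                    D = "acceptor", E = "acceptor",
                    N = "donor_acceptor", Q = "donor_acceptor",
                    H = "donor_acceptor", S = "donor_acceptor",
                    T = "donor_acceptor", Y = "donor_acceptor",
                    A = "none", C = "none", F = "none", G = "none",
                    I = "none", L = "none", M = "none", P = "none",
                    V = "none"),
  polarity = c(R = "polar", N = "polar", D = "polar", Q = "polar",
               E = "polar", H = "polar", K = "polar", S = "polar",
               T = "polar", Y = "polar", C = "polar",
               A = "nonpolar", G = "nonpolar", I = "nonpolar",
               L = "nonpolar", M = "nonpolar", F = "nonpolar",
               P = "nonpolar", V = "nonpolar", W = "nonpolar"))

#' Per-position biochemical class proportions
#'
#' Maps the amino-acid frequencies of a [position_profile()] through fixed
#' amino-acid class tables (hydropathy, size, chemical class, charge,
#' hydrogen donor/acceptor, polarity). Class proportions per property per
#' position sum to 1.
#'
#' @param profile a `position_profile`
#' @param properties subset of property names (default all)
#' @return named list of class x position matrices
#' @export
biochem_profile <- function(profile, properties = names(AA_CLASSES)) {
  out <- list()
  for (prop in properties) {
    map <- AA_CLASSES[[prop]]
    classes <- sort(unique(map))
    m <- matrix(0, nrow = length(classes), ncol = ncol(profile),
                dimnames = list(classes, colnames(profile)))
    for (cl in classes) {
      aa <- names(map)[map == cl]
      m[cl, ] <- colSums(profile[aa, , drop = FALSE])
    }
    out[[prop]] <- m
  }
  out
}

#' Pairwise Spearman correlation of gene usage across samples
#'
#' Genes whose mean usage across samples is at or below
#' `min_mean_fraction` are excluded. 95% confidence intervals use the
#' Fisher transform.
#'
#' @param usage samples x genes matrix from [usage_matrix()]
#' @param min_mean_fraction inclusion threshold on mean usage
#'   (default 0.05)
#' @return data.frame `gene_a`, `gene_b`, `rho`, `ci_lo`, `ci_hi`
#' @export
usage_correlation <- function(usage, min_mean_fraction = 0.05) {
  keep <- colMeans(usage) > min_mean_fraction
  m <- usage[, keep, drop = FALSE]
  genes <- colnames(m)
  n <- nrow(m)
  rows <- list()
  if (length(genes) >= 2L) {
    for (a in seq_len(length(genes) - 1L)) {
      for (b in (a + 1L):length(genes)) {
        rho <- stats::cor(m[, a], m[, b], method = "spearman")
        if (!is.na(rho) && abs(rho) < 1 && n > 3L) {
          z <- atanh(rho)
          se <- 1 / sqrt(n - 3L)
          ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
        } else ci <- c(NA_real_, NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = genes[a], gene_b = genes[b], rho = rho,
          ci_lo = ci[1L], ci_hi = ci[2L], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      rho = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0)))
  }
  do.call(rbind, rows)
}
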