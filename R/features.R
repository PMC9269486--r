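## Five-feature repertoire summaries and their principal component
## analysis, plus per-sample clonality summaries.

#' Compute the repertoire feature vector for one sample
#'
#' The five features are: frequency-weighted mean CDR3 amino-acid length;
#' V-region mutation proportion (summed mutations over summed aligned V
#' length, count-weighted across clonotypes); the resampled mean inverse
#' Simpson index; one minus the resampled mean normalized Shannon-Wiener
#' index; and the Gini index of the raw clonotype counts.
#'
#' @param table a `clonotype_table` (must carry `v_mutations` and
#'   `v_aligned_length`)
#' @param diversity data.frame of resampled estimates for this sample
#'   (rows of `resampled_diversity()$estimates`); when `NULL` the indices
#'   are computed from the raw counts without resampling
#' @return one-row data.frame of class `repertoire_features`, or `NULL`
#'   with a warning when the normalized Shannon index is undefined
#' @export
compute_features <- function(table, diversity = NULL) {
  df <- table$clonotypes
  if (nrow(df) == 0L) stop("empty clonotype table")
  wlen <- sum(df$freq * nchar(df$cdr3aa))
  vm <- if (all(is.na(df$v_mutations))) NA_real_ else {
    sum(as.numeric(df$count) * df$v_mutations, na.rm = TRUE) /
      sum(as.numeric(df$count) * df$v_aligned_length, na.rm = TRUE)
  }
  if (is.null(diversity)) {
    ix <- diversity_indices(df$count)
    inv_simpson <- ix$inv_simpson
    norm_sh <- ix$normalized_shannon
  } else {
    pick <- function(name) {
      v <- diversity$mean[diversity$sample_id == table$sample_id &
                            diversity$timepoint == table$timepoint &
                            diversity$chain == table$chain &
                            diversity$index == name]
      if (length(v) == 1L) v else NA_real_
    }
    inv_simpson <- pick("inv_simpson")
    norm_sh <- pick("normalized_shannon")
  }
  if (is.na(norm_sh)) {
    warning("normalized Shannon undefined for ", table$sample_id,
            "; sample dropped from feature analysis")
    return(NULL)
  }
  gini <- diversity_indices(df$count)$gini
  out <- data.frame(sample_id = table$sample_id,
                    timepoint = table$timepoint, chain = table$chain,
                    weighted_mean_cdr3_len = wlen,
                    v_mutation_proportion = vm,
                    inv_simpson_mean = inv_simpson,
                    one_minus_norm_shannon = 1 - norm_sh,
                    gini = gini, stringsAsFactors = FALSE)
  class(out) <- c("repertoire_features", class(out))
  out
}

FEATURE_COLUMNS <- c("weighted_mean_cdr3_len", "v_mutation_proportion",
                     "inv_simpson_mean", "one_minus_norm_shannon", "gini")

#' Principal component analysis of repertoire features
#'
#' Features are centered and scaled to unit variance (correlation PCA).
#' Sign convention: within each component the largest-magnitude loading is
#' made positive. Variable contributions are squared loadings as a
#' percentage of their component's total.
#'
#' @param features data.frame with the five feature columns (plus optional
#'   id columns, carried into the scores)
#' @return list with `scores`, `loadings`, `percent_variance`,
#'   `contributions`
#' @export
repertoire_pca <- function(features) {
  m <- as.matrix(features[, FEATURE_COLUMNS])
  if (nrow(m) < 3L) stop("PCA needs at least three samples")
  if (anyNA(m)) stop("missing feature values")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(FEATURE_COLUMNS[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  contrib <- apply(pc$rotation, 2L, function(l) 100 * l^2 / sum(l^2))
  scores <- cbind(features[, setdiff(names(features), FEATURE_COLUMNS),
                           drop = FALSE],
                  as.data.frame(pc$x))
  list(scores = scores, loadings = pc$rotation, percent_variance = pv,
       contributions = contrib)
}

#' Top clonotype and top VJ pair of a sample
#'
#' @param table a `clonotype_table`
#' @return list with `top_clonotype` (v, j, cdr3aa, frequency) and
#'   `top_vj` (v, j, frequency); ties break deterministically by key order
#' @export
clonality_summary <- function(table) {
  df <- table$clonotypes
  if (nrow(df) == 0L) stop("empty clonotype table")
  ord <- order(-df$freq, df$v, df$j, df$cdr3aa)
  top <- df[ord[1L], ]
  vj <- vj_pairing(table, weighted = TRUE, min_fraction = 0)
  full <- attr(vj, "full")
  list(top_clonotype = list(v = top$v, j = top$j, cdr3aa = top$cdr3aa,
                            frequency = top$freq),
       top_vj = list(v = full$v[1L], j = full$j[1L],
                     frequency = full$fraction[1L]))
}
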