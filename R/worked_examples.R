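## Bundled worked examples: representative clonotype-level summaries for a
## healthy canine control cohort, at the granularity the verification
## suite checks (gene and family usage marginals, common-CDR3 fractions).

#' Common CDR3 sequences of the bundled control cohort
#'
#' Ranked CDR3 amino-acid sequences per chain with their occurrence count
#' across controls, summed read counts, and pooled percent fraction.
#' Suitable input for [top_clone_fractions()] via its `fraction` column.
#'
#' @param chain optional chain filter (IGH/IGK/IGL)
#' @return data.frame with `sequence`, `chain`, `n_samples`,
#'   `total_count`, `fraction` (percent)
#' @export
common_cdr3_table <- function(chain = NULL) {
  path <- system.file("extdata", "common_cdr3_controls.tsv",
                      package = "bcrflow", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Build clonotype rows realizing the given V/D/J marginal counts (any
## feasible joint distribution works: usage statistics only consume the
## marginals). Greedy transportation fill.
joint_from_marginals <- function(v_counts, j_counts, d_counts = NULL,
                                 chain = "IGH") {
  total <- sum(v_counts)
  stopifnot(sum(j_counts) == total,
            is.null(d_counts) || sum(d_counts) == total)
  if (is.null(d_counts)) d_counts <- stats::setNames(total, NA_character_)
  v <- rep(names(v_counts), v_counts)
  j <- rep(names(j_counts), j_counts)
  d <- rep(names(d_counts), d_counts)
  key <- paste(v, j, d, sep = "\t")
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), "\t", fixed = TRUE))
  df <- data.frame(v = parts[, 1L], j = parts[, 2L],
                   d = ifelse(parts[, 3L] == "NA", NA_character_,
                              parts[, 3L]),
                   count = as.integer(agg), stringsAsFactors = FALSE)
  clonotype_table(v = df$v, j = df$j,
                  cdr3aa = sprintf("WE%05d", seq_len(nrow(df))),
                  count = df$count, d = df$d, chain = chain,
                  sample_id = "controls")
}

#' Worked-example usage tables for the bundled control cohort
#'
#' Clonotype tables realizing the cohort's functional-clone gene-usage
#' marginals: 74,165 heavy-chain reads (V genes dominated by IGHV4-1 and
#' the IGHV3 family, IGHJ4 as the major J, and a D-unassigned class) and
#' 261,806 lambda reads dominated by the IGLV1 family.
#'
#' @return named list of `clonotype_table`s (`IGH`, `IGL`)
#' @export
control_usage_tables <- function() {
  igh_v <- c("IGHV1-1" = 259L, "IGHV3-38" = 19363L, "IGHV3-5" = 39292L,
             "IGHV4-1" = 15251L)
  igh_j <- c("IGHJ4" = 49422L, "IGHJ1" = 24743L)
  igh_d <- c("IGHD4" = 18397L, "IGHD2" = 16955L, "IGHD1" = 10241L,
             "IGHD3" = 8660L, "IGHD5" = 8043L, "IGHD6" = 4993L)
  igh_d <- c(igh_d, stats::setNames(sum(igh_v) - sum(igh_d),
                                    NA_character_))
  igl_v <- c("IGLV1-1" = 202245L, "IGLV8-1" = 40202L, "IGLV3-1" = 15572L,
             "IGLV2-1" = 1981L, "IGLV4-1" = 1632L, "IGLV5-1" = 174L)
  igl_j <- c("IGLJ7" = 261806L)
  list(IGH = joint_from_marginals(igh_v, igh_j, igh_d, chain = "IGH"),
       IGL = joint_from_marginals(igl_v, igl_j, chain = "IGL"))
}
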