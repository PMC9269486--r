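## Small sequence helpers shared by the simulator and the pipeline.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#' @param x character vector of A/C/G/T strings
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide strings (frame 0, trailing partial codon dropped)
#'
#' @param x character vector of nucleotide strings
#' @return character vector of amino-acid strings; stop codons are `*`
#' @export
translate_nt <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return("")
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate random DNA strings
#' @param n number of strings
#' @param len length of each string
#' @return character vector
#' @export
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

## Random codon strings that contain no stop codon (frame 0).
random_codons <- function(n_codons) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  ok <- setdiff(all_codons, STOP_CODONS)
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

## Apply per-base substitution errors (uniform over the three alternatives)
## to a vector of sequences. Returns the mutated vector.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  seqs
}

## Zero-truncated Poisson draws via the inverse CDF.
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0L, lambda), 1)
  stats::qpois(u, lambda)
}

## Stable pmin-style check of probabilities.
check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
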