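## Germline V/(D)/J/C reference handling.
##
## Coordinates are 0-based, half-open everywhere in the codebase; IMGT
## position labels (104, 105-117, 118) are used in reporting only. A V gene
## carries the 0-based offset of the first base of its conserved CDR3-start
## cysteine codon (IMGT 104); a J gene carries the offset of the conserved
## tryptophan/phenylalanine codon (IMGT 118). Anchors always come from the
## annotation table; they are never rediscovered by motif search.

#' Construct a germline reference object
#'
#' @param genes data.frame with columns `name`, `chain`, `segment`,
#'   `family`, `functional`, `anchor_offset`, `sequence`. Constant-region
#'   stubs use `segment == "C"` with the isotype label as `name`.
#' @param validate check invariants (default TRUE)
#' @return an object of class `germline_reference`
#' @export
germline_reference <- function(genes, validate = TRUE) {
  stopifnot(is.data.frame(genes))
  req <- c("name", "chain", "segment", "family", "functional",
           "anchor_offset", "sequence")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols)) {
    stop("missing reference columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- genes[, req]
  rownames(genes) <- NULL
  ref <- structure(list(genes = genes), class = "germline_reference")
  if (validate) validate_reference(ref)
  ref
}

#' @export
print.germline_reference <- function(x, ...) {
  tab <- table(x$genes$chain, x$genes$segment)
  cat("germline_reference:", nrow(x$genes), "records\n")
  print(tab)
  invisible(x)
}

#' Validate germline reference invariants
#'
#' Checks unique names, the A/C/G/T alphabet, that every V anchor codon
#' translates to cysteine and every J anchor codon to tryptophan or
#' phenylalanine, that families prefix their gene names, and that every
#' chain present has at least one V and one J (plus one D for IGH).
#'
#' @param ref a `germline_reference`
#' @return the reference, invisibly; errors name the offending gene
#' @export
validate_reference <- function(ref) {
  g <- ref$genes
  if (anyDuplicated(g$name)) {
    stop("duplicate gene name(s): ",
         paste(unique(g$name[duplicated(g$name)]), collapse = ", "))
  }
  if (any(nchar(g$sequence) == 0L)) {
    stop("empty sequence for gene(s): ",
         paste(g$name[nchar(g$sequence) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGT]", g$sequence)
  if (any(bad)) {
    stop("non-ACGT characters in gene(s): ",
         paste(g$name[bad], collapse = ", "))
  }
  notpre <- substr(g$name, 1L, nchar(g$family)) != g$family
  if (any(notpre)) {
    stop("family is not a prefix of the gene name for: ",
         paste(g$name[notpre], collapse = ", "))
  }
  for (i in which(g$segment %in% c("V", "J"))) {
    off <- g$anchor_offset[i]
    if (is.na(off)) {
      stop("missing anchor offset for ", g$segment[i], " gene ", g$name[i])
    }
    if (off + 3L > nchar(g$sequence[i])) {
      stop("anchor codon out of bounds for gene ", g$name[i])
    }
    codon_aa <- translate_nt(substr(g$sequence[i], off + 1L, off + 3L))
    if (g$segment[i] == "V" && codon_aa != "C") {
      stop("V gene ", g$name[i], " anchor codon is not cysteine (got ",
           codon_aa, ")")
    }
    if (g$segment[i] == "J" && !codon_aa %in% c("W", "F")) {
      stop("J gene ", g$name[i],
           " anchor codon is not tryptophan/phenylalanine (got ",
           codon_aa, ")")
    }
  }
  for (ch in unique(g$chain)) {
    seg <- g$segment[g$chain == ch & g$segment != "C"]
    if (!any(seg == "V") || !any(seg == "J")) {
      stop("chain ", ch, " must have at least one V and one J gene")
    }
    if (ch == "IGH" && !any(seg == "D")) {
      stop("chain IGH must have at least one D gene")
    }
  }
  invisible(ref)
}

#' Look up genes by chain and segment
#' @param ref a `germline_reference`
#' @param chain one of IGH/IGK/IGL (optional)
#' @param segment one of V/D/J/C (optional)
#' @param functional_only keep functional genes only (default FALSE)
#' @return data.frame of matching gene records
#' @export
get_genes <- function(ref, chain = NULL, segment = NULL,
                      functional_only = FALSE) {
  g <- ref$genes
  if (!is.null(chain)) g <- g[g$chain %in% chain, , drop = FALSE]
  if (!is.null(segment)) g <- g[g$segment %in% segment, , drop = FALSE]
  if (functional_only) g <- g[g$functional, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Look up a single gene record by name
#' @param ref a `germline_reference`
#' @param name gene name
#' @return one-row data.frame
#' @export
gene_by_name <- function(ref, name) {
  i <- match(name, ref$genes$name)
  if (is.na(i)) stop("unknown gene: ", name)
  ref$genes[i, , drop = FALSE]
}

#' Constant-region primer signatures per isotype
#'
#' The reverse sequencing mate starts inside the constant region, so its
#' first bases are the reverse complement of the 3' end of the isotype's
#' constant-region stub. Those prefixes act as the isotype "master barcode".
#'
#' @param ref a `germline_reference` with constant (`segment == "C"`) records
#' @param sig_len signature length in nt (default 20)
#' @return named character vector, one signature per isotype
#' @export
isotype_signatures <- function(ref, sig_len = 20L) {
  cg <- get_genes(ref, segment = "C")
  if (nrow(cg) == 0L) stop("reference has no constant-region records")
  sig <- vapply(cg$sequence, function(s) {
    n <- nchar(s)
    revcomp(substr(s, max(1L, n - sig_len + 1L), n))
  }, character(1), USE.NAMES = FALSE)
  stats::setNames(sig, cg$name)
}

#' Write a reference as FASTA plus anchor annotation TSV
#'
#' @param ref a `germline_reference`
#' @param fasta_path output FASTA path (all gene and constant sequences)
#' @param anchors_path output tab-separated annotation path with header
#'   `name chain segment family functional anchor_offset`
#' @return invisibly, the two paths
#' @export
write_reference <- function(ref, fasta_path, anchors_path) {
  g <- ref$genes
  seqs <- Biostrings::DNAStringSet(g$sequence)
  names(seqs) <- g$name
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  ann <- g[, c("name", "chain", "segment", "family", "functional",
               "anchor_offset")]
  utils::write.table(ann, anchors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, anchors = anchors_path))
}

#' Load a germline reference from FASTA + anchor TSV
#'
#' Every FASTA record must have a matching row in the annotation table and
#' vice versa; anchor invariants are checked on load.
#'
#' @param fasta_path FASTA of gene sequences
#' @param anchors_path TSV with header
#'   `name chain segment family functional anchor_offset`
#' @return a validated `germline_reference`
#' @export
load_reference <- function(fasta_path, anchors_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(seqs)
  if (anyDuplicated(nm)) {
    stop("duplicate gene name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  ann <- utils::read.delim(anchors_path, stringsAsFactors = FALSE)
  req <- c("name", "chain", "segment", "family", "functional",
           "anchor_offset")
  if (!identical(names(ann), req)) {
    stop("anchor table must have columns: ", paste(req, collapse = ", "))
  }
  missing_ann <- setdiff(nm, ann$name)
  if (length(missing_ann)) {
    stop("missing anchor row for: ", paste(missing_ann, collapse = ", "))
  }
  missing_seq <- setdiff(ann$name, nm)
  if (length(missing_seq)) {
    stop("anchor row without FASTA record: ",
         paste(missing_seq, collapse = ", "))
  }
  ann <- ann[match(nm, ann$name), ]
  ann$sequence <- as.character(seqs)
  ann$functional <- as.logical(ann$functional)
  ann$anchor_offset <- as.integer(ann$anchor_offset)
  germline_reference(ann)
}

#' Build a deterministic toy germline reference
#'
#' Generates in-frame V genes terminating in a conserved TGT/TGC cysteine
#' codon a few codons before their 3' end, J genes opening with a short
#' CDR3 contribution followed by the conserved TGG (heavy) or TTT/TTC
#' (light) anchor codon and an in-frame FR4 tail, D genes for IGH, and one
#' 60-nt constant-region stub per isotype. Families are assigned
#' round-robin. Pseudogenes (functional = FALSE) can be mixed in; they are
#' excluded from simulation draws by default but remain alignable.
#'
#' @param seed RNG seed; output is reproducible for a fixed seed
#' @param n_v V genes per chain
#' @param n_d D genes (IGH only)
#' @param n_j J genes per chain
#' @param v_len V gene length in nt (multiple of 3)
#' @param chains chains to generate (default IGH, IGK, IGL)
#' @param n_families number of V families per chain
#' @param pseudo_fraction fraction of V genes flagged non-functional
#' @param c_len constant-region stub length
#' @return a validated `germline_reference`
#' @export
build_toy_reference <- function(seed = 1L, n_v = 6L, n_d = 4L, n_j = 4L,
                                v_len = 288L, chains = CHAINS,
                                n_families = 3L, pseudo_fraction = 0,
                                c_len = 60L) {
  stopifnot(n_v >= 1L, n_j >= 1L, v_len %% 3L == 0L)
  set.seed(seed)
  rows <- list()
  add <- function(name, chain, segment, family, functional, anchor, seqn) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, chain = chain, segment = segment, family = family,
      functional = functional, anchor_offset = anchor, sequence = seqn,
      stringsAsFactors = FALSE)
  }
  for (ch in chains) {
    fam_id <- rep_len(seq_len(n_families), n_v)
    fam_ct <- integer(n_families)
    for (i in seq_len(n_v)) {
      fam <- fam_id[i]
      fam_ct[fam] <- fam_ct[fam] + 1L
      ## layout: (v_len/3 - 3) framework codons, the Cys codon, then two
      ## codons of germline CDR3 contribution
      cys_off <- v_len - 9L
      body <- random_codons(cys_off %/% 3L)
      cys <- sample(c("TGT", "TGC"), 1L)
      tail <- random_codons(2L)
      functional <- stats::runif(1) >= pseudo_fraction
      add(sprintf("%sV%d-%d", ch, fam, fam_ct[fam]), ch, "V",
          sprintf("%sV%d", ch, fam), functional, cys_off,
          paste0(body, cys, tail))
    }
    for (j in seq_len(n_j)) {
      ## 9 nt of CDR3 contribution, anchor codon, then 21 nt FR4 tail
      pre <- random_codons(3L)
      anchor <- if (ch == "IGH") "TGG" else sample(c("TTT", "TTC"), 1L)
      fr4 <- random_codons(7L)
      add(sprintf("%sJ%d", ch, j), ch, "J", sprintf("%sJ", ch), TRUE, 9L,
          paste0(pre, anchor, fr4))
    }
    if (ch == "IGH") {
      for (d in seq_len(n_d)) {
        add(sprintf("IGHD%d", d), "IGH", "D", "IGHD", TRUE, NA_integer_,
            random_dna(1L, sample(12:18, 1L)))
      }
    }
  }
  iso <- c(IGH = NA, IGK = "IGK", IGL = "IGL")
  wanted <- unlist(lapply(chains, function(ch) {
    if (ch == "IGH") HEAVY_ISOTYPES else ch
  }))
  for (is in wanted) {
    add(is, isotype_chain(is), "C", is, TRUE, NA_integer_,
        random_dna(1L, c_len))
  }
  germline_reference(do.call(rbind, rows))
}
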