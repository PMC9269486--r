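Package: bcrflow
Title: UMI-Based B-Cell Receptor Repertoire Analysis with a Ground-Truth Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of 5'RACE, UMI-tagged B-cell receptor (BCR)
    repertoire sequencing data: germline V/(D)/J/C reference handling with
    IMGT-style CDR3 anchor coordinates, molecular-identifier-group (MIG)
    consensus error correction, paired-read merging, V(D)J annotation with
    CDR3 extraction, clonotype assembly with quality filters, and repertoire
    statistics (segment usage, VJ pairing, spectratypes, CDR3 composition and
    sequence-logo information content, Hill diversity profiles with
    resampling, repertoire overlap, and repertoire-feature principal
    component analysis). Includes a synthetic repertoire and read simulator
    that emits ground truth alongside FASTQ output so every pipeline stage
    can be validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
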