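---
title: "Methods: UMI-based BCR repertoire analysis in bcrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UMI-based BCR repertoire analysis in bcrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bcrflow` analyses B-cell receptor (BCR) repertoires sequenced with a
5'RACE protocol in which the template-switch oligo (TSO) stamps an 8-nt
unique molecular identifier (UMI) onto every cDNA molecule. This
vignette documents the models, the parameters that matter, and the
numerical and design choices, so results can be interpreted and the
limits of the built-in simulator understood.

## The data model

A sequenced molecule is
`TSO tail + UMI + V(D)J junction + constant-region segment`. The forward
mate reads the TSO tail, UMI and the 5' end of the junction; the reverse
mate starts inside the constant region and reads back across the J-C
boundary into the CDR3. Three facts anchor the analysis:

* the UMI identifies a single cDNA molecule, so reads sharing a UMI are
  replicates of one molecule (a molecular identifier group, MIG) and can
  be collapsed to an error-corrected consensus;
* the start of the reverse mate carries the isotype's constant-region
  signature (IGM/IGG/IGA/IGE for heavy chains; IGK/IGL label the light
  loci), so class can be assigned before any alignment;
* the CDR3 is delimited by two conserved residues whose positions are
  known in the germline genes — the framework-3 cysteine (IMGT position
  104) in every V gene and the tryptophan/phenylalanine (IMGT 118) in
  every J gene.

All coordinates in the codebase are 0-based and half-open; IMGT position
labels appear only in reporting. Anchor coordinates are always taken from
the reference annotation table and projected through alignments — they
are never rediscovered by motif search, which would introduce an
unspecified heuristic.

## Pre-processing: isotype, UMI, MIG, consensus, merging

Reads are processed in a fixed order: isotype assignment (unique
signature match on the reverse-mate prefix with at most 2 substitutions;
ties and non-matches are "unassigned"), UMI extraction (TSO tail located
at the read start allowing one mismatch), per-pair mate merging, MIG
assembly, consensus calling.

**Merging before consensus.** Mates of each pair are merged over their
best ungapped overlap (identity maximised; at least 20 nt of overlap; a
pair merges when identity is at least 70%). Pairs that fail to merge
contribute their forward insert only. MIG consensus is then taken over
the merged per-pair sequences. The opposite order (consensus per mate,
then one merge per MIG) is equally defensible; the package fixes this
order so that runs are reproducible and the attrition semantics are
unambiguous. The 20-nt overlap floor exists to prevent spurious
"70%-of-3-bases" merges.

**MIG size threshold.** Groups are keyed by (isotype class, UMI),
matched exactly — no edit-distance UMI collapsing is attempted, since
the error model that would justify it is not part of the contract; UMI
collisions are permitted and reported instead (their expected number
follows the birthday bound `m(m-1)/2 / 4^L`). The default minimum MIG
size of 3 trades error-correction strength for repertoire coverage: size
3 is the smallest group in which a single erroneous read is outvoted.

**Consensus.** Members are restricted to the modal length (a MIG whose
modal-length members are fewer than half the group is discarded as
incoherent); each position takes the plurality base, ties broken by
summed base quality and then lexicographically. For per-base error
`e` and MIG size 3, the probability that at least two members are wrong
at a position is `3e^2(1-e) + e^3` — about `3.0e-4` at `e = 0.01`,
versus `1e-2` uncorrected. This closed form is an upper bound on the
realized consensus error: when the two wrong reads disagree with each
other, the three-way tie is sometimes resolved in favour of the true
base, so measured rates fall at or slightly below the bound. The
acceptance checks compare against the bound at three binomial standard
errors over at least 10^5 consensus bases.

## Annotation

Consensus sequences are aligned locally (Smith-Waterman, affine gaps)
against every germline gene of their chain; scoring is match +2,
mismatch -3, gap open 6, gap extend 1, and a hit must reach
`0.4 * match * min(len(query), len(gene))` to count. The top score wins;
ties break by fewer mismatches, then by locus order, so runs are
reproducible. The test suite holds the aligner to score equality with an
independently written brute-force dynamic-programming oracle on hundreds
of random instances.

The CDR3 is extracted by projecting the V gene's Cys104 offset and the J
gene's anchor offset through their alignments. The anchored CDR3 runs
from the cysteine codon through the Trp/Phe codon inclusive; the short
CDR3 (IMGT 105-117) drops both anchors and is the clonotype key. One
generic correction is applied: if the projected anchored CDR3 begins
X-C — a leading residue in front of the conserved cysteine, the
signature of an off-by-one anchor annotation seen in some species'
lambda records — the leading residue is trimmed. Expressing the fix as a
sequence rule rather than a chain-specific hack means it self-disables
on correctly annotated references.

A sequence is functional when its anchored CDR3 length is a multiple of
three and the translation, in the cysteine's frame from the start of the
V alignment to the end of the J alignment, contains no stop codon.
D genes are reported (best ungapped exact match of at least 5 nt in the
inter-V-J region, with a "D not identified" class) but never enter the
clonotype key: D segments are short and readable in multiple frames, so
D calls are far less reliable than V/J calls.

## Clonotypes and QC

A clonotype is the triple (V gene, J gene, short CDR3 amino-acid
sequence); heavy-chain isotypes are concatenated into a single IGH table,
non-functional clonotypes are kept in a parallel partition, and
frequencies are computed within the functional partition. QC boundaries
are read literally: a sample-timepoint-chain dataset is excluded when it
has *fewer than* 1,000 error-corrected reads (999 is excluded, 1000
kept) or *more than* 95% of reads failed to define clonotypes (exactly
95.0 is kept). The denominator for the unassigned percentage is the MIG
consensus count — the number of error-corrected sequences entering
annotation.

## Repertoire statistics

* **Segment usage** is a normalized per-gene (or per-family) proportion,
  weighted by clone counts or counting each clonotype once; D-unassigned
  is its own category. Cross-sample comparisons Z-score each gene across
  samples (a zero-variance gene maps to all-zero scores rather than NaN)
  and cluster with Euclidean distance and complete linkage.
* **VJ pairing** fractions are computed over all pairs before any
  filter; the reporting filter keeps pairs strictly above 1%.
* **Spectratype**: per-sample clone-frequency-weighted CDR3-length
  distributions averaged with equal sample weight (not read-weighted, so
  a deep sample cannot dominate the cohort); mean proportions below
  1e-5 are dropped as likely artefacts.
* **Common-CDR3 ranking** pools counts across samples: a sequence's
  fraction is its summed count over all reads in the included tables.
  A mean-of-per-sample-fractions alternative would weight small samples
  up; pooling is the default because it reproduces the bundled worked
  examples exactly. Cumulative top-n figures can also be computed from a
  supplied fraction column, which makes them independent of the pooling
  scheme.
* **Position profiles** keep CDR3s of one fixed length per chain (the
  modal length; with or without the two anchor flanks), average
  per-sample frequencies with equal weight, and label columns with IMGT
  positions. Sequence-logo letter heights use Shannon information
  `R = log2(20) - H` with no small-sample correction; biochemical class
  profiles map the frequencies through fixed IMGT-style amino-acid class
  tables shipped in the package.
* **Usage correlation**: Spearman rank correlation between genes whose
  mean usage exceeds 5%, with Fisher-transform 95% intervals.

## Diversity

The index battery: observed richness; Shannon entropy (natural log);
normalized Shannon `H / ln S`, flagged undefined when `S <= 1` (it is
defined at `S = 2` and the package computes it there); inverse Simpson
`1 / sum p_i^2`; Chao1 `S + f1^2 / (2 f2)` with the bias-corrected form
`S + f1(f1-1) / (2(f2+1))` when `f2 = 0`; an Efron-Thisted
unseen-species estimate as the Euler transform of the alternating
frequency-of-frequencies series at fixed depth 20 (clamped non-negative
so the estimate never falls below observed richness); d50 as the minimal
number of top clonotypes reaching half the reads (a clonotype count, not
a normalized variant); and the Gini index
`sum_ij |x_i - x_j| / (2 n^2 xbar)`.

**Resampling.** Within a comparison group, tables with fewer than 100
clonotypes are excluded (small clone sets make the resampling estimates
unstable), remaining tables are down-sampled at read level without
replacement to the smallest clone-set size in the group, indices are
recomputed, and the procedure repeats 1,000 times to give a mean and SD.
Read-level sampling without replacement makes the expected downsampled
richness exactly the multivariate hypergeometric form
`sum_i 1 - C(N - n_i, k) / C(N, k)`, which the tests verify.

**Hill profiles.** `D_a = (sum p_i^a)^(1/(1-a))` on the grid 0 to 10 in
steps of 0.2. `D_0` is richness and `D_2` the inverse Simpson index. At
`a = 1` the formula is undefined; the package uses the continuity limit
`exp(H)`, which keeps the profile continuous and non-increasing, and
exposes a raw-entropy mode for compatibility with plots that show `H`
itself at that point. Profiles are compared by Euclidean distance with
complete-linkage clustering. Group comparisons use the Wilcoxon
signed-rank test (paired) or Mann-Whitney-Wilcoxon rank-sum test with
Bonferroni adjustment `min(1, m p)`.

## Overlap and repertoire features

Two clonotypes overlap only on an exact key match — an identical CDR3
with a different V or J is a different clonotype. Overlap reports the
Jaccard index over keys, the shared proportion of each table, and a
least-squares regression of shared clonotypes' log10 frequencies
(table B on table A), fitted only when at least three clonotypes are
shared. Log space is used because shared-clone frequencies span orders
of magnitude; the slope-1 reference line is the same in either space,
and a linear-space mode is available.

The per-sample feature vector for PCA: frequency-weighted mean CDR3
amino-acid length; V-region mutation proportion (summed mutations over
summed aligned V length, count-weighted — a per-clone unweighted mean is
not used because deep clones carry most of the evidence); resampled mean
inverse Simpson; one minus resampled mean normalized Shannon; and Gini
from the raw clonotype counts. Mixing resampled means with a raw-count
Gini mirrors common practice but does mean the features are not all on
the same sampling footing. Features are centred and scaled (correlation
PCA) since they live on incommensurate scales; the sign convention makes
each component's largest-magnitude loading positive; variable
contributions are squared loadings as a percentage of their component.
Samples whose normalized Shannon is undefined are dropped from the PCA
with a logged reason.

## The simulator: what it emulates, and what it does not

`simulate_repertoire()`/`synthesize_reads()` generate ground truth down
to the molecule: clone frequencies (uniform, power-law, or a
dominant-clone spike, e.g. 95.4% for a monoclonal lymphoma sample),
V/J usage bias, geometric junctional trimming capped so anchors survive,
Poisson N-additions, substitution-only SHM in the V region, a
configurable lambda:kappa molecule ratio defaulting to 0.91 (the lambda
bias reported for dogs), multinomial molecule assignment, uniform-random
8-nt UMIs with collisions permitted, zero-truncated Poisson reads per
molecule, and independent per-base read errors.

Defaults for junctional diversity (`trim_p = 0.5`,
`n_insert_mean = 4`) and SHM (`shm_rate = 0.01` per base) are
placeholders at plausible magnitudes — no canine-specific estimates are
available to calibrate them, and analyses should treat them as knobs,
not biology. SHM avoids substitution targets that would create an
in-frame stop codon: functional receptors are stop-free by construction,
and this keeps the per-base mutation count exactly binomial instead of
biased low by resampling.

The simulator does **not** model template-switch artefacts, truncated
transcripts, chimeric reads, index hopping, PCR amplification bias
within a MIG, indel sequencing errors, or biased (non-uniform) error
substitution. Consequently, green tests certify the pipeline's
correctness under the stated error model — they do not certify
performance on libraries dominated by those artefacts. Reads-per-molecule
is zero-truncated Poisson because only the MIG-size threshold matters
downstream; any amplification model with the right mass at ≥3 reads
would behave identically.

## Problem sizes and determinism

The verification suite runs at deliberately modest sizes chosen to keep
every check sharp but fast on one CPU: 10^4 molecules (~5x10^4 read
pairs) for end-to-end dominant-clone recovery, 1.2x10^5 consensus bases
for the error closed form, 1,000 resampling iterations, 200 random
aligner-oracle instances, and twelve simulated samples (spike fractions
0.75-0.95 versus power-law) for the clonality-separation PCA. All
randomness flows from explicit seeds; pipelines rerun byte-identically
under a fixed configuration.

## Known limitations

* Alignment is substitution-oriented; indel-rich reads (not produced by
  the default simulator) will be annotated conservatively or dropped at
  the score floor.
* The IGL-style anchor correction handles a one-residue offset only; a
  reference whose anchors are wrong by more than one codon needs fixing
  in the annotation table, which is the coordinate authority.
* Efron-Thisted at fixed Euler depth is one member of a family of
  estimators; depth is configurable but 20 is not data-adaptive.
* Clonotype keys are amino-acid level; nucleotide-level clonotyping and
  clonal-lineage inference are out of scope.
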