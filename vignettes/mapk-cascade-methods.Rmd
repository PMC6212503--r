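---
title: "Methods: motif-grammar mining, duplication and expression analysis of MAPK cascade families"
author: "mapkcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-grammar mining, duplication and expression analysis of MAPK cascade families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

MAPK cascades transduce stress and hormone signals through three
consecutive serine/threonine kinases: MAPKKK phosphorylates MAPKK, which
dual-phosphorylates MAPK on the threonine and tyrosine of its activation
loop. `mapkcascade` implements a complete desk pipeline for characterizing
these three families in a plant genome: identification by motif grammar,
subgroup placement by phylogeny, gene-structure and chromosomal context,
tandem-duplication detection with Ka/Ks-based selection inference, promoter
cis-element profiling, and transcriptional profiling from tag counts and
qRT-PCR.

Because the original study's inputs (a published genome assembly and SRA
runs) are external resources, the package pairs every analysis stage with a
synthetic-corpus generator that plants the study's composition; the
pipeline is then verified by blind recovery of the planted design.

# The motif grammar

Families are defined by degenerate motifs, compiled from the field's
notation (`x` any residue, `(A/B)` alternatives, `x{m,n}` bounded gap)
into anchored regular expressions:

* **MAPK** — the activation loop in its full context
  `-T(E/D)YVxTRWYRAPE(L/V)-`. The residue at position 2 distinguishes the
  TEY loop (groups A–C) from the TDY loop (group D). A bare `TxY`
  tripeptide outside this context never qualifies. Group-C members
  additionally carry the C-terminal common-docking (CD) domain
  `-LHDxx(E/D)EPxC-`, which we require to lie in the C-terminal half of
  the protein; we read `E/D` as a one-position alternative, the most
  direct reading of the published alignments.
* **MAPKK** — all three of the catalytic site `-VGTxxYMSPER-`, the active
  site `-D(L/I/V)K-` and the phosphorylation target `-(S/T)xxxxx(S/T)-`.
  The `S/T` gap is fixed at five residues by default (the operative form
  used during identification), with the bounded-gap form `x{3,5}`
  available through the pattern language where the looser variant is
  wanted.
* **MAPKKK** — exactly one of the subfamily signatures: MEKK
  `-G(T/S)Px(W/Y/F)MAPEV-`, RAF `-GTxx(W/Y)MAPE-`, ZIK
  `-GTPEEMAPE(L/V/M)(Y/F/L)-`. The RAF consensus is strictly the least
  specific of the three (a MEKK instance such as `GTPAWMAPEV` also matches
  it), so signatures are evaluated in the specificity order MEKK, ZIK,
  RAF; all matches are recorded and genuinely conflicting sites are
  flagged rather than discarded.

Families are tested in the priority order MAPK, MAPKK, MAPKKK. A minimum
length of 200 aa serves as a proxy for the 200–300 aa kinase domain that
every genuine member carries; profile-HMM and external domain-database
verification are out of scope, so the flag column lets users post-verify
borderline calls. Upstream of the grammar the pipeline mirrors the
reference workflow with a redundancy-removal step (pairwise identity and
mutual coverage at or above 99%, keep the longest, lexicographic
tie-break) and a reference-panel identity screen (best global-alignment
identity at or above 50% against any labeled reference), which stands in
for the HMM-search stage of the original workflow using that workflow's
own identity criterion.

# Alignment and phylogeny

Pairwise alignment is global Needleman–Wunsch with affine gaps (Gotoh),
implemented in C++ on a precomputed column-score matrix; a gap run of
length *k* costs `gapOpen + k * gapExtend`, defaulting to BLOSUM62 with
10/0.5 — ClustalW-era protein defaults, configurable. Traceback tie-breaks
are deterministic (diagonal, then up, then left). Identity is matches over
alignment columns; coverage is residue-to-residue columns over the longer
sequence length.

Multiple alignment is progressive: a guide tree from average-linkage
clustering of pairwise identity distances, profiles merged with
profile-to-profile NW where a column pair scores the mean substitution
score over residue pairs. Distances from alignments are p-distances over
gap-free column pairs, with an optional Poisson correction `-ln(1 - p)`
(flagged infinite at p = 1). Trees are neighbor-joining; the
implementation delegates the Saitou–Nei agglomeration to `ape::nj` and
clamps negative branch-length estimates to zero with a flag. The distance
model used by the original study's tree software is not stated, so the
default (uncorrected p-distance) is declared in output metadata rather
than presented as the original setting. Bootstrap support resamples
alignment columns with replacement, rebuilds the NJ tree per replicate,
and reports the fraction of replicates containing each original
bipartition, under a caller-supplied seed.

Group assignment for MAPKs/MAPKKs places each candidate on an NJ tree with
a labeled reference panel (one or more references per group A–D) and takes
the majority label of the candidate's sister clade after rooting at the
reference farthest from the candidate; ties are reported `unassigned`. A
TDY activation loop short-circuits to group D, which is that loop's
defining property.

# Duplication and Ka/Ks

Duplicate pairs are called within families when a global alignment covers
more than 70% of the longer sequence at more than 70% identity. The third
criterion of the reference workflow — one duplication event for tightly
linked genes — is stated there without a definition; we operationalize it
by collapsing chains of pairwise-qualifying genes lying within the tandem
distance on one linkage group into single best-partner events (greedy by
identity, deterministic id tie-break). Tandem status itself is same
linkage group within 100 kb; the threshold is configurable and the
synthetic corpus places tandem pairs under 50 kb so recovery is
threshold-insensitive.

Ka/Ks is classic NG86: per-codon synonymous site fractions (mutations to
stop codons count as nonsynonymous, which keeps N + S exactly 3 per
codon), averaged over both sequences; observed differences averaged with
equal weight over all minimal substitution pathways, excluding pathways
through stop codons; Jukes–Cantor correction `-(3/4) ln(1 - (4/3) p)`,
flagged undefined at p ≥ 3/4. Ks = 0 yields an undefined ratio (NA), never
an infinite sentinel. Codon alignments come from back-translating the
protein alignment (PAL2NAL-style), and columns containing a gap are
excluded from all counts. Transition/transversion weighting and codon
models beyond NG86+JC are deliberately out of scope, and the output
metadata labels the method as NG86.

# Promoters

Promoters are the 1.5 kb immediately 5' of the translation start (ATG) on
the coding strand — the anchor the reference workflow states explicitly —
reverse-complemented for minus-strand genes and truncated (with a flag) at
contig edges. Scanning is dictionary-based: each element is a named IUPAC
consensus matched exactly on both strands, one count per distinct
(element, start, strand), palindromic double-hits counted once. The
original study names its elements but not their consensus strings, and
cis-element databases drift between versions, so the dictionary ships as
an editable TSV (`inst/extdata/cis_elements.tsv`) rather than hard-coded
patterns; the packaged strings are standard plant-promoter consensus
forms. The CGTCA- and TGACG-motifs are exact reverse complements, so a
double-strand scan necessarily reports both at every occurrence of either;
the generator's bookkeeping and all recovery counts account for this.

# Expression

Tag counts normalize to FPKM (`count * 1e9 / (librarySize * length)`) or
TPM (length-normalized rates rescaled to one million per sample; columns
sum to 1e6 within 1e-6 relative tolerance). A gene is "detected" at FPKM
at or above 1 by default; the generator separates expressed genes (FPKM
well above 5) from silent ones (exact zeros), so recovery of the detection
design is insensitive to any floor in (0, 5).

The reference study cites its differential-expression machinery without
specifying the test, so the package implements the classic two-library
tag-count test of that era, the Audic–Claverie conditional probability,
evaluated in log space. The two-sided p doubles the smaller of the two
directional tails (the lower tail of y given x, and of x given y in the
mirrored orientation) counting the observed point once; for equal
libraries it is symmetric in (x, y) and equals the conditional probability
0.5 at x = y = 0. Calls require BH-adjusted p < 0.05 and |log2 fold
change| ≥ 1 of library-normalized rates at **every** compared time point
(12/24/48 h), matching a design in which reported genes respond across
the whole course; both thresholds live in the configuration, and the
generator plants five-fold effects robust to any reasonable choice.

Heatmap profiles are per-gene z-scores of `log2(TPM + 1)` — the
legend-level description "normalized log2 TPM" admits per-gene or global
scaling, and per-gene is chosen and flagged in metadata — ordered by
average-linkage clustering on `1 - Pearson r`, zero-variance genes flagged
with all-zero profiles. qRT-PCR analysis is 2^-ddCt with a reference gene
per replicate, a paired two-sided t-test across replicates against the
control condition (three replicates by default), and stars at p < 0.05 /
p < 0.01; zero-variance replicate sets return NA with a flag rather than
a fabricated p.

# The synthetic corpus: what it emulates, and what it does not

`generatorParams()` defaults encode the reference composition: 12 MAPKs
(groups A/B/C/D = 1/1/5/5), 5 MAPKKs (1/1/1/2), 65 MAPKKKs (16 MEKK, 40
RAF, 9 ZIK), 100 motif-free decoys, 22 tandem duplicate pairs (3 MAPK, 19
MAPKKK), promoter prevalences (HSE 66/82; ARE 8/12, 4/5, 54/65; LTR 5/12,
2/5, 22/65; one designated 27-element promoter on a MAPKK), tissue
detection 74 in all three tissues / 5 partial / 3 silent, and a cold
course with 33 genes nonzero throughout, 10 up- and 11 down-regulated.
Gene structures draw exon counts from the published per-group ranges
(group A 18 exons, B 3, C 6–7, D 10–12; MEKK 1–17; RAF 3–17 plus a single
51-exon outlier; ZIK 3–9).

Design choices a user should know:

* **Ancestor-derived families.** Members of a group/subfamily derive from
  a shared random ancestor by point substitution at rate 0.25 per site,
  with the family's motif instances overwritten at fixed relative
  positions and rejection sampling against the classifier's own rules.
  This puts member–reference identity near 75% (safely above the 50%
  screen) and member–member identity near 57% (safely below the 70%
  duplication criterion). The reference panel is the ancestors themselves.
* **Pairs evolve at the codon level.** A partner is the member's CDS run
  through proposal–acceptance evolution: substitutions to stop codons are
  rejected, synonymous changes always accepted, nonsynonymous changes
  accepted with probability equal to the configured dN/dS (0.2 by
  default), motif codons masked, stopping at 85% protein identity. All
  defaults were fixed from the design, before any acceptance measurement.
* **Decoys are kinase-length but motif-free**, verified by rejection
  against the full family rules; a harder decoy tier carries a bare TEY
  without its context to exercise the full-context rule.
* **Promoter backgrounds are element-free by construction** (scan-repair
  until clean, then planting, then a verification rescan that must match
  the expected counts exactly), so recovered prevalences equal planted
  prevalences without tolerance.
* **Back-translation** uses the standard code with uniform synonymous
  codon choice; no codon-usage model is imposed.
* **Expression counts are Poisson** around design means (detected genes
  50–500 expected counts at a declared library size of 1e6; up-regulated
  genes rise five-fold, down-regulated fall five-fold), with the design
  made exact rather than almost-sure: cells the truth table declares
  expressed are clamped to at least one count.

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show: there is no sequencing-read level (counts are
drawn, not mapped), no overdispersion beyond Poisson, no indel evolution
within pairs, no paralogy gradients between the planted classes (decoys
are unrelated rather than kinase-homologous), no intergenic gene content,
and no UTRs in the synthetic gene models (promoters anchor at the ATG,
which coincides with the gene start there). Recovery on this corpus
demonstrates that the pipeline measures what was planted — correctness of
the machinery — not that the thresholds would reproduce the counts on a
real genome.

# Problem sizes and determinism

The shipped test-suite and acceptance runs use the full default corpus
(182 proteins, 82 gene models on 11 linkage groups, ~0.4 Mb of genome,
three tissues, four cold time points) — the study-scale design, which
completes in minutes on one CPU. Oracle suites run at the sizes where
exhaustive computation is feasible: all-alignment enumeration for
sequences up to length 6, all 61x61 sense-codon pairs for NG86 pathway
counts, 50 random additive trees (up to 8 taxa) for NJ recovery, a
2000-replicate null simulation for the tag-test type-I error, and
fine-grid scans of the charge curve for pI. Every stochastic component
(generator, bootstrap, simulations) takes an explicit integer seed, and a
fixed parameter set plus seed reproduces the corpus byte-identically.

# Known limitations

* The motif grammar is a literal implementation of the published
  consensus strings; real proteomes contain family members with degenerate
  activation loops that only profile methods would recover.
* The identity screen depends on the reference panel's coverage; a family
  absent from the panel cannot survive screening.
* NG86 saturates for deeply diverged pairs (flagged); no maximum-likelihood
  codon model is provided.
* The Audic–Claverie test models single libraries per condition; with
  biological replicates a dispersion-aware model would be preferable.
* The promoter scanner is exact-consensus (IUPAC) matching; no
  position-weight-matrix scoring.
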