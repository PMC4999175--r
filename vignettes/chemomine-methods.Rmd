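---
title: "chemomine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemomine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomine)
```

This vignette documents the models and procedures implemented in
`chemomine`, the assumptions behind them, and the design decisions taken
where more than one defensible choice existed. It states no empirical
result beyond what the package's tests and acceptance script themselves
compute.

## The scientific setting

Aphids and other hemipterans detect host plants, alarm pheromone and mates
through proteins of the antennal sensillum lymph: odorant-binding proteins
(OBPs) and chemosensory proteins (CSPs). Both families are short secreted
proteins whose paralogs diverge heavily in sequence (often <30% pairwise
identity) while conserving a scaffold of disulfide-bonded cysteines. Family
membership is therefore diagnosed from the *spacing* of conserved
cysteines, not from overall similarity. Catalogue studies of a new species
typically proceed: assemble a transcriptome, find ORFs, scan translations
for the spacing motifs, confirm candidates, then characterize them by
identity matrices, NJ trees, abundance (RPKM) between morphs, and qPCR
profiles across tissues and developmental stages. `chemomine` implements
that analysis chain from the ORF stage onward; read cleaning, assembly and
homology annotation are out of scope.

## Motif model and scanner

A motif is an ordered list of anchors (single residues, `C` or `P` in the
built-ins) with an inclusive gap range between consecutive anchors, parsed
from a PROSITE-like dialect: `C-x(22,32)-C-...`, where `x(n)` abbreviates
`x(n,n)` and adjacency (`C-P`) means a gap of exactly 0.

Two semantic choices matter:

* **Gap residues are unrestricted.** `x(n,m)` means "between n and m
  residues of any kind", including further anchor letters. A cysteine-rich
  protein can then satisfy a pattern through several different anchor
  assignments, and a left-to-right greedy matcher (or a regular expression
  with greedy/lazy quantifiers) can commit to an assignment that fails
  later even though another assignment succeeds.
* **Any-assignment semantics.** A protein carries the motif iff at least
  one assignment exists.

`scan_motif()` therefore backtracks over candidate anchor positions with
two prunings (gap-range violation; not enough residues left for the
remaining minimum gaps and tail) and enumerates *all* distinct assignments
in lexicographic position order. Enumeration is capped at 10,000
assignments per protein with a warning; the cap exists for pathological
cysteine-rich synthetic input and is far above anything a real precursor
produces. The test suite proves the scanner exhaustive by comparing it
against an independent brute-force enumerator on hundreds of random and
planted proteins up to 120 aa.

The five built-in patterns (`motif_library()`):

| name | pattern |
|---|---|
| `OBP_GENERAL` | `C-x(15,39)-C-x(3)-C-x(21,44)-C-x(7,12)-C-x(8)-C` |
| `OBP_CLASSIC` | `C-x(22,32)-C-x(3)-C-x(36,46)-C-x(8,14)-C-x(8)-C` |
| `OBP_PLUSC` | `C-x(20,41)-C-x(3)-C-x(41,46)-C-x(19,29)-C-x(9)-C-x(8)-C-P-x(9,10)-C-x(9,10)` |
| `CSP_METHODS` | `C-x(6,8)-C-x(16,21)-C-x(2)-C` |
| `CSP_RESULTS` | `C-x(5,6)-C-x(18,19)-C-x(2)-C` |

Design notes:

* The two CSP variants circulate side by side in the literature (a broader
  and a tighter spacing); both ship built in and the active one is a
  configuration choice. The default is `CSP_RESULTS`, the tighter pattern,
  which the known aphid CSPs all satisfy.
* In the Plus-C pattern the conserved proline immediately follows C6 (gap
  0), and the final `x(9,10)` is a *tail* requirement: at least 9 residues
  must follow the last cysteine. The right boundary of a trailing gap is
  not meaningfully enforceable on a precursor of arbitrary C-terminal
  length, so only the minimum is required and the match span ends at the
  final anchor.
* Scanning is performed on the full precursor, signal peptide included.
  Catalogue lengths are precursor lengths, and the first cysteine of all
  built-in patterns sits well downstream of typical signal peptides, so
  pre-cleavage scanning changes nothing for these families.
* The classic hemipteran ranges overlap the general insect ranges but
  neither contains the other (e.g. a C3–C4 spacing of 45 is classic but
  not general; a spacing of 25 is general but not classic). Each motif is
  therefore tested independently, and `classify_protein()` reports a flag
  set plus a primary family by the fixed precedence
  Plus-C > classic > general > CSP.

## ORF discovery

`find_orfs()` enumerates, on both strands and all three frames:

* complete ORFs, ATG → next in-frame stop;
* stop-less ORFs, ATG → sequence end (3'-truncated assemblies);
* the frame-initial segment reaching a stop without beginning at ATG
  (5'-truncated assemblies), reported with `has_start = FALSE`.

All ATGs are considered as starts (nested ORFs are enumerated; the longest
wins at selection time). Coordinates are reported 1-based inclusive on the
forward strand — the natural R/Bioconductor convention (`IRanges`-style) —
and translation uses the standard genetic code only, with codons containing
`N` rendered `X` and a trailing partial codon dropped. "Complete ORF" means
both start and stop present. The default minimum protein length `min_aa =
80` leaves margin below the smallest known mature OBP/CSP precursors
(~110 aa) while suppressing spurious short ORFs. Whether UTR-internal ATGs
should be excluded is unknowable without cloning evidence; considering all
ATGs and selecting the longest product is the conservative choice and is
what the planted-recovery tests pin down.

## Comparative analysis

**Pairwise identity.** End-to-end (global) Needleman–Wunsch/Gotoh alignment
with affine gap cost `open + k·extend`, implemented in C++ (`src/align.cpp`)
with a deterministic traceback preference (diagonal, then gap-in-second,
then gap-in-first). Defaults mirror classic progressive-alignment penalties
— gap open 10, extension 0.2 — with an identity substitution scheme (match
+1, mismatch 0); all four are configurable. Identity is `100 × identical
columns / alignment length`, gap columns counted in the denominator. The
aligner is verified against exhaustive alignment enumeration for short
sequences.

**Multiple alignment.** Tree building consumes an externally produced
alignment when one exists. The built-in fallback is center-star: the
sequence with maximal summed identity is the center, all others are aligned
to it pairwise, and the pairwise alignments are merged under "once a gap,
always a gap". Center-star is adequate at the scale of a family catalogue
(tens of sequences); it is not a substitute for a progressive aligner on
large or deeply diverged sets, and the tests that need a *correct*
alignment use the simulator, which introduces no indels.

**Distances.** p-distance: differing columns over columns where neither
sequence is gapped. The distance model behind published NJ trees of these
families is usually unstated; p-distance is the simplest defensible default
and the matrix input to `nj_build()` is explicit, so any other protein
distance can be substituted. p-distance need not be metric; NJ does not
require it.

**Neighbour joining.** Saitou–Nei agglomeration with
`Q(i,j) = (r−2)d(i,j) − Σd(i,·) − Σd(j,·)`, standard branch-length
formulas, the three-point closed form for the final trifurcation, negative
branch lengths clamped to 0, and ties in Q broken by the lexicographically
smallest pair of subtree representative labels (the smallest leaf label
under each working node). The clamp and tie-break make output
bit-reproducible; on additive matrices neither engages, and the tests
verify exact recovery (topology, and path lengths to 1e-9) on random
additive matrices of 4–8 taxa, cross-checked against an independent NJ
implementation.

**Bootstrap.** Columns resampled with replacement under a single integer
seed; each replicate goes through p-distance and NJ; the support of each
internal edge of the original tree is the percentage of replicates whose
tree contains the same unrooted leaf bipartition. A replicate in which some
pair has no comparable columns cannot yield a distance matrix; such
replicates are skipped with a warning and excluded from the denominator
(with 1000 replicates and any realistic alignment this is a non-event; the
alternative, counting skips as non-support, would silently deflate
supports). Supports are attached as integer node labels and survive the
newick writer, which quotes labels containing metacharacters and prints
branch lengths to 6 significant digits.

## Quantification and qPCR

**RPKM.** `RPKM = (10^6 × C × 10^3)/(N × L)` exactly; no pseudo-counts.
`C = 0` reports 0, and between-condition ratios with a zero denominator
report `Inf` (or `NaN` for 0/0) rather than shifting the scale. Library
size N is supplied separately from the count table because the total of
uniquely aligned reads is a property of the library, not the sum of the
genes one happens to tabulate.

**Standard curves.** Ct is regressed on log10 input by OLS; efficiency in
percent is `100(10^(−1/slope) − 1)` and the assay passes in the 90–110%
window (slope −3.3219 ↔ 100%). Positive slopes are reported with a warning
and `passes = FALSE`.

**Relative quantification.** Technical replicates are averaged to one Ct
per biological sample; biological samples are the units of all downstream
statistics (the conservative reading when a design reports both technical
and biological triplicates). Per gene, `Q = E^(Ct_min − Ct)` with `Ct_min`
that gene's minimal mean Ct across samples and E the gene's amplification
factor — default 2 (100% efficiency), since assays are typically validated
into the efficiency window rather than published with per-gene E. The
normalization factor NF of a sample is the geometric mean of the reference
genes' Q there; normalized expression is Q/NF. Because a loading shift adds
the same ΔCt to every gene of a sample, it multiplies all Q of that sample
by the same factor and cancels exactly in Q/NF — the scale-invariance the
tests verify to machine precision. Fold changes are relative to a
configurable calibrator sample.

**ANOVA + LSD.** Classical one-way ANOVA (fitted with `aov`; the F is
verified against brute-force sums of squares in the tests), then Fisher's
LSD: groups differ iff `|mean_i − mean_j| >
t(1−α/2, df_error)·sqrt(MSE(1/n_i + 1/n_j))`, α = 0.05 by default. Letters
come from insert-and-absorb over groups sorted by descending mean, so
non-different groups share a letter. The ANOVA runs on raw normalized
quantities by default (whether published analyses log-transform is usually
unstated); log-transform the `norm` column first if desired. Degenerate
conventions: zero within-group variance with unequal means reports
`F = Inf`, p = 0, letters from the exact ordering (the LSD threshold is 0,
so any mean difference separates); all-identical groups report `F = 0`,
p = 1, one shared letter — the 0/0 F is resolved to "no evidence of
difference".

## The synthetic-data generators

Every generator is a pure function of its design and an integer seed; a
shared base seed is expanded by fixed per-component offsets so adding a
generator never perturbs existing fixtures.

* `plant_motif()` places anchors at exact gaps; fill residues exclude the
  spec's anchor letters by default, making the planted assignment provably
  unique (correctness tests), with `exclude_anchors = FALSE` for stress
  tests where alternative assignments arise.
* `perturb_gap()` builds negative controls by pushing one spacing outside
  its range — mirroring the real deviant precursors whose C1–C2 spacing of
  49 residues excludes them from the general pattern.
* `gen_transcript_set()` reverse-translates with uniform synonymous codons
  (codon usage is irrelevant to every tested property), wraps ORFs in
  random UTRs, and rejection-samples the UTRs until the planted protein is
  exactly the transcript's longest ORF — recovery is then guaranteed by
  construction, which is what an end-to-end recovery test needs.
  Negatives are nucleotide shuffles re-drawn until they contain no
  classifiable candidate.
* `sim_counts()` draws `C ~ Poisson(rpkm × N × L/10^9)` and records N as
  the library size. The recovery tests use 1000 genes with true RPKM
  between ~5 and 1000 (the realistic range for expressed chemosensory
  genes in antennal libraries), L between 500 and 2000 bp, N = 10^6.
* `sim_ct_table()` writes `Ct = base − log_E(fold) + shift + ε`,
  ε ~ N(0, sd), with reference genes at fold 1 and a per-sample loading
  shift shared across genes — exactly the structure multi-reference
  normalization assumes and cancels.
* `sim_alignment_on_tree()` evolves a root sequence along a known tree
  with per-site substitution probability `1 − exp(−rate × length)` and no
  indels, so the true alignment and the true topology are known.

What the generators deliberately do **not** emulate: read-level sequencing
noise and assembly artifacts, indel evolution, codon usage, reference-gene
instability, and inter-gene correlation. Passing tests therefore
demonstrate algorithmic correctness under the stated statistical structure,
not robustness to violations of it on real data.

### Synthetic accession stand-ins

`synthetic_accession_set()` rebuilds, from a catalogue of 18 deposited
OBP/CSP records (accessions KU140605–KU140622), one transcript per gene
whose longest-ORF protein reproduces the record's published precursor
length, ORF completeness and cysteine-spacing class — including the nine
classic-motif OBPs, the two Plus-C OBPs, the two deviant-spacing OBPs
(C1–C2 of 49 and C4–C5 of 21 in one; C3–C4 of 47 in the other), and the
five CSPs. These are *synthetic surrogates* built from published catalogue
metadata: they exercise the full mining pipeline offline, but agreement
with the deposited nucleotide sequences themselves is only testable after
fetching them (`scripts/fetch_accessions.R`).

## Problem sizes and determinism

The shipped test-suite sizes are chosen to finish in a few minutes on one
CPU while keeping every check statistically decisive: scanner-vs-oracle on
500 random + 200 planted proteins (≤120 aa); NJ recovery on 100 random
additive matrices (4–8 taxa); RPKM recovery on 1000 genes (expected
3-standard-error coverage ≥99.5% at these expression levels, asserted
≥99%); bootstrap demonstrations at 100–200 replicates (the user-facing
default remains 1000); qPCR fold recovery at Ct noise sd 0.05 with 3
technical replicates, asserted within 10%. All randomness flows through
explicit integer seeds; identical seeds give byte-identical outputs.

## Known limitations

* Center-star alignment quality degrades on deeply diverged sets; supply a
  proper multiple alignment for publication-grade trees.
* The motif formalism covers anchor/gap patterns only — no profile or HMM
  scoring, no signal-peptide prediction, no homology confirmation; those
  steps complement, not replace, motif evidence in a real catalogue.
* p-distance saturates for distant proteins; the NJ input is an explicit
  matrix precisely so corrected distances can be swapped in.
* RPKM comparisons are descriptive (ranking, ratios); no count-model
  differential-expression testing is provided, and none of the qPCR
  statistics corrects across genes for multiple testing.
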