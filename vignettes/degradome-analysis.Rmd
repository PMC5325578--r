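---
title: "Calling miRNA cleavage targets from degradome (PARE) libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling miRNA cleavage targets from degradome (PARE) libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paredeg)
```

## The measurement and the model

Degradome (PARE) sequencing captures the uncapped, polyadenylated 5'
ends of mRNA decay fragments. In plants, an Argonaute loaded with a
miRNA slices its target between the nucleotides paired with miRNA
positions 10 and 11, leaving a 3' fragment with a 5'-monophosphate.
Each sequenced 20-21 nt tag therefore marks, with single-nucleotide
precision, a position where an mRNA was cut. Evidence for a miRNA
target is the conjunction of two independent observations:

1. **Sequence**: a window of the transcript pairs well with the miRNA
   under the plant-specific penalty scheme (below), with canonical
   Watson-Crick pairs opposite miRNA positions 10 and 11.
2. **Degradome support**: the 5' ends of tags pile up exactly at the
   transcript position paired with miRNA position 10.

The pipeline chains the standard stages: adapter clipping, quality/N
filtering to 20-21 nt clean tags, collapsing to unique tags with raw
counts, TP100M normalisation (`count / clean_total * 1e8`),
priority-rule classification against tiered ncRNA references
(Rfam-like classes first, then GenBank-like, then the polyN rule, then
the transcriptome), exact sense mapping, duplex search, cleavage-site
calling with a five-category peak classification, and an explicit
permutation p-value.

## Duplex scoring

The penalty table is the Allen-style scheme universally used for plant
miRNA/target pairing: mismatch +1, G:U wobble +0.5, each gapped or
bulged nucleotide +1, and every penalty doubled when the miRNA
position lies in the core region 2-13. At most one single-nucleotide
gap (unpaired miRNA base) or bulge (extra target base) is allowed per
duplex. A candidate requires a total score of at most 7. Pairing is
antiparallel: miRNA position 1 pairs the 3'-most base of the target
window.

Two readings of "no mismatch at the cleavage site" are possible; we
take the strict one: positions 10 and 11 must be canonical Watson-Crick
pairs, with G:U and gaps both disallowed there. A bulge directly
between positions 10 and 11 is likewise rejected. For bulges we must
also decide which position's core status doubles the penalty; we
double it only when both flanking miRNA positions lie in 2-13. These
conventions are applied identically in the scanner and in the
brute-force oracle the tests compare it against.

The search itself is an exhaustive scan of every window of length L,
L-1 and L+1 (for the gap and bulge variants) with no heuristic
seeding: at the scale of a transcriptome search with 21-nt queries,
exactness is affordable (the inner loop is compiled) and guarantees
the enumeration-oracle equivalence that the tests assert.

```{r}
path <- rep("WC", 21); path[5] <- "mismatch"
score_duplex(path)    # doubled inside the core
```

## Peak categories

Every called site is placed in one of five classes computed from the
transcript's profile of raw tag counts. Only *occupied* positions
(count >= 1) enter the computation; in particular the median is taken
over occupied positions. Including empty positions would drive the
median to zero on virtually every transcript and make the "at or below
the median" class unreachable, which cannot be the intent of the
published rules.

* **0** - count >= 2, equal to the transcript maximum, unique maximum;
* **1** - count >= 2, equal to a maximum attained more than once;
* **2** - count >= 2, below the maximum, above the median;
* **3** - count >= 2, at or below the median;
* **4** - exactly one raw tag.

"More than one raw tag" is read strictly (count >= 2); a single-tag
site is category 4 regardless of peak shape. Raw counts, not TP100M,
feed the comparisons. Ties where the site equals both maximum and
median resolve in ladder order (0/1 before 2/3). Multi-mapping tags
contribute their full count at every occurrence.

## Empirical p-values

The published record tables carry p-values whose computation is not
specified, so the package substitutes an explicit, reproducible
permutation null: the miRNA sequence is shuffled preserving
mononucleotide composition, the full search-and-call procedure is
re-run against the transcript set, and

\[ p = \frac{1 + k}{1 + R} \]

where k of R shuffles produce a call at least as good as the observed
record (score no larger *and* category no larger). The add-one
estimator keeps p in (0, 1]. The default is R = 100; the analysis
scripts use R = 50, which already separates planted perfect sites
(p about 0.02) from the 0.05 threshold. No multiple-testing correction
is applied, matching the published use of raw p <= 0.05.

## The synthetic study conditions

The generator is first-class, tested code: it is the only way the
pipeline can be exercised end to end with known truth, since the
original raw libraries are not shipped. Its defaults define the study
conditions used by the tests and the acceptance script: 20 transcripts
of 300-600 nt, 5 miRNAs of 21 nt with two planted sites each, planted
raw counts of 5-30 (about 175 signal reads), background at 0.02 tags
per transcript nt, and contaminants off unless configured. Planted
windows are exact reverse complements of the miRNA with the configured
edits applied; the truth record's expected score is always computed by
the scoring oracle from the edit list, never hand-entered.

Determinism is strict: a fixed seed yields byte-identical FASTQ
output. Reads extend 20 or 21 nt 3'-ward from the cleavage site (a
seeded coin flip per read, mirroring MmeI-truncated tag lengths); the
generator places sites far enough from transcript ends that no read is
truncated. Low-quality reads carry three Phred-2 bases, N-reads
exactly one N, and polyN reads are built with 16/21 identical bases
(76%, strictly above the 70% rule). Background placements are
re-rolled so they never land on a planted site, never reach the
smallest planted count on their transcript, and never multi-map, which
keeps the truth categories exact by construction.

What the simulation does *not* emulate - and hence what passing tests
do not show about real data: positional decay gradients along
transcripts, sequencing error, ligation bias, isoform ambiguity, and
near-cognate off-target pile-ups. The simulator validates the
*machinery* (every rule and formula applied correctly), not the
biological error rates of degradome analysis.

## Numerical and design choices

* "Low quality" is undefined in the published accounting; we use: at
  least 3 bases with Phred < 20, or a trimmed length outside 20-21 nt
  (FASTA input skips the Phred clause). Adapter trimming never removes
  a read, so `clean = raw - N - low_quality` holds as an identity.
* Adapter clipping truncates at the first exact occurrence of the
  adapter's first 8 nt.
* polyN tags survive filtering, are counted in the clean total under
  their own class, and are excluded from target mapping.
* ncRNA classification is exact and orientation-insensitive;
  transcript target mapping is exact and sense-only.
* Pair identity for the two-library overlap is (miRNA id, target id),
  ignoring the site coordinate, and each library's overlapped record
  set is computed against its own rows - the published CL/DL overlap
  counts differ (489 vs 485), which is only representable per-library.
  Percentages are printed to 2 decimals with half-up rounding.
* miRNA family names strip trailing variant letters, "-N-" copy
  segments and arm suffixes (`mno-miRn74a-1-3p` belongs to
  `mno-miRn74`); this normalisation is what reproduces the published
  family tallies.
* Score comparisons use a 1e-9 tolerance so the 0.5-grained penalty
  arithmetic is never broken by floating-point noise.
* Degenerate inputs: empty read sets yield an all-zero accounting;
  candidates without tag support are dropped but counted; a missing
  genome turns the strand report into a warning, not an error.

## Problem sizes

The test suite and acceptance script run the full study at the default
scale (20 transcripts, 5 miRNAs, about 200 reads), the
category-ladder equivalence on 1000 random profiles, the
enumeration-oracle equivalence on transcripts of about 150-200 nt, and
the p-value behaviour over 20 replicate simulations at R = 50 - sizes
chosen so the complete analysis reruns from scratch in well under a
minute while still exercising every rule at least once.

## Limitations

Translational repression leaves no degradome signature, so targets
regulated without slicing are invisible here by design. The duplex
scheme scores sequence complementarity only (no thermodynamics). Exact
matching is assumed for 20-21 nt tags throughout, replacing heuristic
short-read alignment; this is correct for clean synthetic data and for
perfect-match analyses, but it will not recover tags carrying
sequencing errors.
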