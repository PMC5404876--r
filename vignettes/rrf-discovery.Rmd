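---
title: "Detecting rRNA-derived fragment series with rrfscan"
author: "rrfscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rRNA-derived fragment series with rrfscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfscan)
```

## The problem

Small RNA sequencing libraries of animal tissue are dominated by
fragments of ribosomal RNA. These rRNA-derived fragments (rRFs) are
conventionally discarded as degradation noise, but a subset of them is
structured: fragments whose 5' end coincides exactly with the 5'
boundary of a mature rRNA gene (rRF5), and fragments whose 3' end
coincides with the gene's 3' boundary (rRF3). Within such a
terminus-anchored group the free end varies, producing a *ladder* of
fragment lengths in consecutive 1-nt steps — a signature that is hard
to reconcile with uniform random degradation, which spreads fragment
ends evenly along the molecule.

`rrfscan` turns that observation into a reusable analysis: it cleans
and collapses an sRNA-seq library, aligns reads to an annotated rDNA
unit allowing at most one mismatch or one 1-nt gap, classifies each
fragment by its termini relative to gene boundaries, groups terminal
fragments into anchored series, measures their 1-bp ladder runs, and
tests terminal enrichment against a uniform-degradation null. A
synthetic-library generator with ground truth makes every stage
testable without any external download.

## The model and its assumptions

**Reference.** A single rDNA transcription unit with ordered,
non-overlapping regions — mature genes (18S, 5.8S, 28S) and internal
transcribed spacers (ITS1, ITS2). Annotation gaps are permitted and
labelled "unannotated" (external transcribed spacers are often
unannotated in user inputs). All internal coordinates are 0-based
half-open; 1-based coordinates appear only in reports and GFF3/SAM
I/O. Boundaries are an explicit input, never inferred: published
mature-rRNA coordinates differ between annotations, so the terminus
definition must be under the user's control.

**Alignment.** "At most one mismatch or one gap" is read literally:
edit distance ≤ 1 with indels restricted to 1 nt, and never a
mismatch and a gap together. The search is seed-and-verify with a
pigeonhole guarantee — an alignment with at most one edit leaves at
least one read half exact, so seeding the leading 7-mer of both
halves on both strands finds every candidate, which is then verified
directly. One best placement is kept per read, with fully
deterministic tie-breaking (lower cost, sense before antisense,
smaller start, mismatch before gap, insertion before deletion). `N`
never matches any base, in reads or reference. External alignments
can be imported from SAM instead; records with ≥ 2 edits, indels
longer than 1 nt, or clipped bases are discarded so both routes
enforce the same contract. Clipped alignments are excluded because a
clipped terminus is not evidence about where the fragment actually
ends.

**Classification.** A fragment contained in a gene is rRF5 when its
5' offset from the gene start is within the tolerance (default 0 —
"precisely aligned"), rRF3 when its 3' offset is within tolerance,
otherwise body. The rRF5 check runs first, so a fragment covering an
entire short gene is rRF5 and flagged full-length. Fragments crossing
a region edge are "spanning" and never counted as terminal: a read
running past a gene's 3' end into the spacer is evidence of a longer
precursor, not of a fragment ending at the boundary. Classification
is computed for *all* genes including 18S; absence of 18S terminal
enrichment is a result, not a rule.

**Series and ladders.** A series is keyed by its anchored boundary
coordinate, not by member sequences, so 1-edit variants aggregate
naturally. Fragment length is the reference span, so a 1-nt-deletion
variant of a 30-nt fragment counts at length 30 — anchors live in
reference coordinates. The ladder statistic is the longest run of
consecutive integer lengths each supported by at least `min_count`
reads (default 1, since published ladders are shown without a depth
threshold). A series is *called* when its run reaches `min_run`
(default 3 — a lone fragment or a pair is never a series) and its
total count reaches `min_total` (default 10). Whether a "series"
requires a contiguous ladder is genuinely open; the run statistic
with a threshold encodes one explicit choice, and both knobs are
exposed.

**Enrichment test.** No specific test is prescribed for "terminal
fragments are more highly expressed than body fragments", so the
package adopts the simplest defensible null: under uniform
degradation, each contained fragment's anchored coordinate (5' start
for the 5' test, 3' end for the 3' test) is uniform over the region's
`L − min_len + 1` admissible positions. The p-value is the one-sided
binomial tail `P[X ≥ observed]` with success probability
`(tol + 1, clipped to the region) / (L − min_len + 1)`, and
Benjamini–Hochberg correction is applied across (gene, terminus)
pairs. The null is slightly approximate — positions near a region's
3' edge admit fewer contained lengths than interior positions, so the
modelled per-position probability is marginally conservative for long
genes and marginally anticonservative for short ones — but the
measured rejection rate at α = 0.05 stays within a few hundredths of
nominal at realistic depths (the acceptance checks measure it on
10,000-fragment background libraries).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_len` | 15 nt | shortest read kept after cleaning |
| `adapter_seed` | 8 nt | minimum adapter overlap to trim (≤ 1 mismatch) |
| `max_n_frac` | 0.10 | maximum tolerated fraction of N bases |
| `k` (`seed_k`) | 7 | aligner seed length; < 7 is rejected as unspecific |
| `end_tolerance` | 0 nt | terminus offset allowed for rRF5/rRF3 calls |
| `min_run` | 3 | consecutive lengths needed for a called series |
| `min_total` | 10 | reads needed for a called series |
| `min_count` | 1 | per-length depth for the ladder run |

Quality filtering is off by default; the Q20 percentage is a reported
statistic, not a filter. All percentages are reported with half-up
rounding (one decimal for rates, two for shares) and every percentage
in `summary.json` is stored next to its numerator and denominator.

## The synthetic generator

`make_toy_reference()` builds a random unit with contiguous regions
in canonical 18S–ITS1–5.8S–ITS2–28S order. The default lengths
(1800, 700, 157, 1100, 3900 nt; ≈ 7.7 kb) approximate a metazoan
rDNA transcription unit, so per-position background depth and
region-relative anchor probabilities are at realistic scale.

`simulate_library()` emulates what the analysis assumes about a real
run: terminus-anchored ladder reads (exact subsequences at every
length in the specified range, Poisson counts per length), a
uniform-breakpoint degradation background (length drawn uniformly in
15–40 nt, then placed uniformly among positions where it fits),
near-exclusive sense origin (default antisense fraction 2 × 10⁻⁴,
mirroring a 99.98%-sense library), per-base substitution error, and
PCR jackpot duplication of selected fragments. Quality strings are
constant Phred 40; QC behaviour is exercised separately with
hand-built FASTQ fixtures. One deliberate modelling choice: the
background places whole fragments inside the molecule rather than
clipping lengths at the reference end, because clipping would pile
fragment 3' ends onto the last coordinate — an artifact, not part of
a uniform-breakpoint null, and one that would sit exactly on the 28S
3' boundary in a flankless toy unit.

What the generator does *not* emulate: sequence-dependent error
profiles, adapter chimeras, ITS-derived planted series, multi-locus
rDNA repeats, and real secondary-structure-driven breakpoint bias.
Passing the synthetic checks therefore demonstrates that the
machinery is correct and calibrated under its stated model; it does
not by itself establish how a particular real library will behave.

## Numerical and degenerate-input choices

* Ties in read collapsing order by descending count, then
  lexicographically (C locale) — outputs are byte-stable.
* An empty library, an empty region table, or zero aligned reads
  produce valid zero-count summaries; ratio statistics signal "not
  computable" instead of dividing by zero.
* Regions with fewer than two admissible anchor positions are
  rejected by the enrichment test as degenerate.
* Reads longer than the reference are unmapped, not an error.
* Repeated runs on identical inputs write byte-identical outputs.

## Problem sizes used in the checks

The test-suite and acceptance runs use libraries of roughly 4,000
reads for ladder recovery (4 planted ladders × 9 lengths × Poisson
mean 100, background at 10% of planted counts, 20 seeds), 200
randomized reference/read cases for aligner–oracle equivalence, and
167 background-only libraries of 10,000 fragments (≥ 1,000
(gene, terminus) tests; the first 100 libraries also feed the
zero-call check). These sizes give stable statistics while keeping a
full run in tens of seconds.

## Known limitations

* Single-sample design: no cross-sample statistics or differential
  expression.
* One rDNA locus: no genome-wide mapping, no multi-copy repeat
  variation.
* The enrichment null ignores within-region breakpoint bias (e.g.
  structure-driven cleavage hot-spots); a hot-spot away from a
  boundary is *not* evidence for a terminal series, and would not be
  called one, but it can inflate the body denominator.
* BWA-compatibility is approximate by construction: BWA breaks
  placement ties randomly, this aligner deterministically; the SAM
  import path exists for parity checks, not byte-parity.
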