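---
title: "Split-read mapping of single-end RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read mapping of single-end RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitmap)
```

## The problem

Most spliced aligners assume that a read's fragments lie collinearly on one
strand of one chromosome, within an intron-sized distance.  Reads from
trans-spliced messages, fusion transcripts and circular RNAs violate every
one of those assumptions: their fragments may map to opposite strands, to
loci hundreds of kilobases apart or on different chromosomes, or in
inverted genomic order (the back-splice signature of circularization).
splitmap maps single-end cDNA reads without any a-priori assumption on the
transcript structure and classifies the resulting junctions as *regular*,
*strand-reversing*, *long-range* (> 200 kb or inter-chromosomal) or
*circular*.

## The pipeline

**Seeding.**  For a read of length $m$ and minimum suffix length $\ell$, at
most $2(m-\ell)$ suffixes of the read and of its reverse complement are
matched against a suffix array of the genome.  Each suffix contributes its
longest exact prefix match as a candidate seed; when the error budget
allows and the locus is unique, the seed is extended through a single
substitution.  After a maximal match the scan resumes at the first
unmatched read position, so one seed per error-free segment is found and
the scan stays linear in practice.  Three filters apply:

* *length*: matches shorter than $\ell$ (default 20 nt) are discarded;
* *occurrence*: seeds occurring more than `max_occurrences` (default 50)
  times are repetitive and discarded;
* *entropy*: the read substring under the seed must have mononucleotide
  Shannon entropy $H(S) = -\sum_i p(s_i)\log_2 p(s_i) \ge 1.5$ bits,
  which removes poly-A and other low-complexity matches that slip past
  the occurrence cap because of sequencing errors.

The jump-ahead rule depends only on the exact-match geometry, never on the
filters, so lowering the entropy threshold can only add seeds and mapping
the reverse complement of a read yields the mirrored seed set.

**Chaining.**  Seeds are sorted by read start; the chain score is
$$\sigma(c) = \sum_k \psi(c[k]) \;-\; \sum_{k\ge2}
\bigl|\,\pi_e(c[k-1]) - \pi_s(c[k])\,\bigr|,$$
where $\psi$ is the seed score (matches minus errors) and $\pi_s,\pi_e$ are
the seed's read coordinates; gaps and overlaps are penalized alike.  A
greedy dynamic program concatenates each seed with its best admissible
predecessor (one whose read end lies strictly before the seed's read end)
whenever that improves the score, using at most $|C|(|C|-1)/2$ pairwise
comparisons.  Only the top-ranking chain proceeds, and only when it covers
more than 80 % of the read; equal-scoring chains prefer fewer fragments,
then the leftmost genomic position.  Multi-locus seeds are then fixed to
single loci so that adjacent seeds minimize genomic distance, preferring
same-chromosome, same-strand placements; the minimization is exhaustive
when at most 256 occurrence combinations exist and a greedy outward fixing
from the least-ambiguous seed otherwise.

**Transition alignment.**  Each chained locus contributes a reference
window: the seed interval extended by `boundary_extension` on both sides,
reverse-complemented for minus-strand seeds.  Chain-adjacent seeds whose
alignment diagonals differ by less than `min_transition_gap` are
continuations of one locus, split only by sequencing errors, and share a
single window — otherwise every error inside an exon would masquerade as a
pair of transitions.  Over the windows, a Smith-Waterman-like local
alignment is computed in a three-dimensional table $M[i,k,j]$ (read
position, window, window position).  Besides the usual local moves
(diagonal $s(a,b)$, indel $-\delta$, floor at 0), a cell may continue from
$\mathrm{lms}[k',i-1] - \tau + s(a,b)$ for any preceding window $k' < k$,
where lms tracks the running maximum of $M$ per window up to each read
row.  With a single window the recursion is exactly Smith-Waterman.  The
traceback of the maximal cell yields an ordered multi-fragment alignment;
every adjacent fragment pair implies one junction.

**Junction calling.**  The donor is the last aligned base of the
earlier-in-read fragment in transcription direction, the acceptor the
first aligned base of the later one.  Classification is purely geometric:
opposite strands give *strand-reversing*; different chromosomes or a span
beyond `long_range_distance` give *long-range*; an acceptor upstream of
its donor (in transcription direction) gives *circular*; the rest are
*regular*.  Observations are aggregated per breakpoint, support summed,
and junctions below `min_support` dropped.

## Breakpoint conventions

Two conventions make breakpoints comparable across reads and against a
truth table at exact (0 nt) tolerance:

* *Orientation normalization.*  The libraries modeled here are not
  strand-specific, so a junction and its reverse-complement observation
  are the same event.  Junctions are stored with the lexicographically
  smaller breakpoint first, flipping both strand flags when the sides are
  swapped; sense and antisense observations then collapse to one record,
  and the class is invariant under the flip.
* *Shift canonicalization.*  When the base closing the donor side equals
  the base just upstream of the acceptor, the split point can sit at
  several positions with identical alignment score.  Junctions are
  therefore shifted, in the normalized frame, as far as the flanking
  sequence allows (up to 100 nt).  The simulator applies the same rule to
  its truth junctions, so ambiguity never shows up as disagreement.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_suffix_length` | 20 | nt | minimum seed length $\ell$ |
| `max_occurrences` | 50 | — | repetitive-seed cap |
| `entropy_threshold` | 1.5 | bits | low-complexity filter |
| `min_accuracy` | 80 | % | minimum identity of a reported alignment |
| `min_coverage` | 0.80 | fraction | read coverage the top chain must exceed |
| `match`, `mismatch`, `indel` | +1, −1, 1 | score | transition-alignment scoring |
| `transition` ($\tau$) | 3 | score | penalty per locus jump |
| `boundary_extension` | 30 | nt | window widening per side |
| `min_fragment_length` | 15 | nt | terminal-sliver trimming |
| `min_transition_gap` | 50 | nt | minimum diagonal shift between loci |
| `long_range_distance` | 200000 | nt | long-range classification bound |
| `min_support` | 1 | reads | junction support filter |
| `merge_tolerance` | 5 | nt | breakpoint consolidation radius |

Two defaults deserve their rationale.  `boundary_extension` must exceed
$\ell$: an error closer than one seed length to a junction truncates the
flanking seed, and a window that stops short of the true boundary forces
the alignment to skip read bases and misplace the junction at the window
edge; 30 nt covers the truncation plus a small indel allowance.
`merge_tolerance` exists because an error *at* the junction base itself
moves that read's breakpoint by a few nucleotides (a local alignment
prefers skipping a base or opening a 1 nt gap over a mismatch); such
observations are consolidated within 5 nt and the cluster reports its
modal breakpoint, so error-free data still yields exact coordinates.

## Numerical and tie-breaking choices

* Scores and the DP are integral; no floating-point tolerances enter the
  alignment.
* Traceback ties prefer diagonal moves and fewer transitions (a transition
  is taken only when strictly better), making output deterministic.
* Chains with equal scores prefer fewer fragments, then the leftmost
  genomic coordinate; occurrence resolution breaks distance ties towards
  same-strand placements, then leftmost positions.
* `N` never matches anything (including `N`), so seeds cannot span
  ambiguity runs; all-`N` reads fail seeding and are reported unmapped.
* Fragments shorter than `min_fragment_length` are trimmed from the
  alignment ends; short middle fragments are kept, since removing them
  would fabricate a junction between their neighbors.
* Degenerate inputs (empty seed set, all-zero DP matrix, sub-threshold
  chain coverage) consistently yield an unmapped read, never an error.

## The simulator

`simulate_genome()` draws i.i.d. uniform A/C/G/T chromosomes (optionally
overwritten with poly-A decoy tracts to exercise the entropy filter).
`simulate_isoforms()` lays out non-overlapping exon chains, flips or
distantly relocates each exon with probability `irregular_fraction`
(default 0.20), optionally circularizes the transcript, and records every
junction with its class as computed by `classify_junction` — the truth
table and the caller share one classification authority.
`simulate_reads()` samples reads uniformly along each transcript (around
the circle for circular ones, so back-splice-spanning reads arise
naturally), reverse-complements half of them, and applies one of two
distributional error models: *illumina* (substitutions 0.004, indels
5×10⁻⁴ each) and *r454* (substitutions 0.002, indels 0.005 each, scaled by
$1 + 0.3\,(\text{homopolymer length} - 1)$), emulating the
substitution-dominated short-read and indel-dominated pyrosequencing
regimes of the standard read simulators.  A read witnesses a junction in
the truth table only when it overlaps both sides by at least `anchor`
(10) nt.  Everything is deterministic given the config seed.

What the simulator does *not* emulate: real exon-length and splice-site
statistics, expression-level variation, position-dependent quality decay,
genomic repeats and paralogy (beyond the occurrence cap's reach), and
library-preparation artifacts.  Passing benchmarks on these synthetic
genomes therefore demonstrates algorithmic correctness of seeding,
chaining, transition alignment and junction calling — not performance on
repeat-rich mammalian genomes.

## Benchmarks

`run_benchmark()` reproduces the simulation protocol end to end at desk
scale — about 2 Mb of genome and 100 isoforms (50 circular plus 50
collinear transcripts in the long-read scenario), 20 % irregular exons in
the mixed datasets, 100 nt substitution-model or 400 nt indel-model reads
at 10× coverage (4× for full-length long reads), evaluated at exact
breakpoint tolerance.  `scripts/acceptance.R` runs all six scenarios and
writes the headline recall/FPR/precision numbers; the test suite runs the
same scenarios at 0.4× size, except the circular-precision check, which
needs the full ~100-isoform size for a single read-level artifact not to
exceed the criterion's resolution.  Runs complete in a few minutes each on
one CPU.

## Known limitations

* The seeder is exact-match based (plus one substitution); very high error
  rates fragment seeds faster than the chain-coverage threshold tolerates.
* Transitions are only permitted forward along the chain order; structures
  requiring revisiting an earlier window within one read rely on the chain
  ordering to expose them.
* A single scalar $\tau$ penalizes all transitions alike, regardless of
  intra- versus inter-chromosomal jumps.
* Gap costs are linear, not affine; base qualities are ignored.
* Junction support counts reads, not distinct alignment positions, so PCR
  duplicates would inflate support on real libraries.
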