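---
title: "Refining viral contigs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining viral contigs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo assemblies of viral genomes from metagenomic short reads are
usually fragmented, and occasionally chimeric: a contig may splice together
sequence from two organisms, or carry a scrambled end where the assembler
stopped prematurely. `viralrefine` takes a single contig plus the read set
it was assembled from and iterates three operations until the contig either
closes into a circle or stops growing:

1. **Circularity check.** Viral genomes are commonly circular (or linear
   with terminal repeats); an assembly that walked all the way around the
   genome carries its own start duplicated at the 3' end. The duplicated
   copy is detected by self-alignment and trimmed, and the contig is
   declared complete.
2. **Coverage audit.** Under shotgun sequencing, a correctly assembled
   contig has approximately uniform per-base depth of coverage. Runs of
   bases whose depth falls outside the central percentile band of the
   contig's own depth distribution ("suspicious regions") are evidence of
   chimerism; the pipeline keeps only the longest clean segment and lets
   extension regrow the rest from reads.
3. **Edge extension.** Reads are recruited to the first and last
   `round(1.5 * read_length)` bases of the contig by shared k-mers (with
   their mates), and a greedy suffix–prefix overlap walk grows each edge
   strictly outward. When nothing grows, increasing amounts (300–2,000 bp)
   are trimmed from both ends and extension is retried once per trim size
   — misassembled ends are the usual cause of a stalled extension.

After the loop the contig is checked for circularity once more and then
polished by pileup majority consensus (substitutions and indels up to
10 bp).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lower_pct`, `upper_pct` | 15, 85 | percentile | normal band of the depth distribution |
| `min_suspicious_len` | 1000 | bp | runs must be strictly longer to be "true suspicious" |
| `edge_factor` | 1.5 | × read length | edge window for recruitment/assembly |
| `trim_schedule` | 300…2000 | bp | symmetric end trims tried after a stall |
| `recruit_k` | 21 | bp | k-mer size for recruitment, seeding, placement probes |
| `min_shared_kmers` | 3 | count | recruitment threshold (≈23 bp edge overlap) |
| `min_overlap` | 30 | bp | smallest usable suffix–prefix overlap |
| `max_mismatch_rate` | 0.02 | fraction | overlap acceptance during assembly |
| `circ_identity`, `circ_aln_frac` | 0.95, 0.95 | fraction | circularity alignment thresholds |
| `min_depth`, `min_majority` | 5, 0.7 | count, fraction | polishing floor and majority rule |
| `max_iterations` | 100 | rounds | loop cap |

## Percentile bands with heavy ties

Depth vectors are integer-valued and heavily tied — most dramatically when
a chimeric insert has no read support at all, so that a large fraction of
bases sits at depth exactly 0. A naive nearest-rank percentile of the
sorted depth vector then *returns 0 as the lower bound*, the band becomes
`[0, ub]`, and the very signal the audit exists to find becomes invisible
(for an 8 kb zero-support insert in a 38 kb chimera, 21% of bases are 0,
which swallows a 15th percentile cut entirely).

`viralrefine` therefore classifies bases by a tie-aware (midrank)
percentile rank: a base with depth `d` has rank
`100 * (count(depth < d) + 0.5 * count(depth == d)) / n`, and is suspicious
when that rank falls outside `[lower_pct, upper_pct]`. Equivalently, the
band is the interval of depth *values* whose midrank lies inside the band;
`compute_depth()` reports those two values as `lower_bound`/`upper_bound`.
This keeps the two important degenerate cases sensible:

* a constant profile has midrank 50 everywhere — nothing is suspicious;
* a tie block straddling the lower cut is classified as a block (all
  suspicious when its midrank is below the cut), rather than silently
  becoming the bound itself.

The "longer than 1,000 bp" rule is read strictly: a run of exactly
1,000 bp is not a true suspicious region.

## Circularity: seeds in the probe window, evidence on the diagonal

With contig length `L_s` and read length `L_r`, the probe window
`G_a = [L_s - 2 L_r, L_s - L_r)` is matched against the body
`G_b = [0, L_s - 2 L_r)` by exact 21-mer seeds. Each seed fixes an
ungapped diagonal; along that diagonal the detector looks for an alignment
window of at least `ceil(0.95 * L_r)` columns at ≥ 95% identity and then
grows the window base-by-base in both directions while the running
identity stays at or above the threshold, yielding the maximal repeat
pair. Two deliberate choices:

* **The qualifying window may extend beyond the probe window.** The probe
  is an arbitrary 150 bp slice of a repeat that can be thousands of bases
  long; confining the identity evidence to the slice makes detection of a
  degraded repeat a coin flip near the threshold (the identity of a 150 bp
  window under 4% mutation is `Binomial(150, 0.96)`-distributed and falls
  below 95% in roughly a quarter of draws). Anchoring on the seed but
  scoring the whole diagonal keeps the thresholds meaningful while using
  all the evidence.
* **Only the forward strand can trigger a trim.** A circular permutation
  cannot present reverse-complemented terminal redundancy without
  misassembly; inverted terminal repeats are reported
  (`inverted_repeat_hint`) but never trimmed.

The **downstream (3') copy** of the repeat is removed, keeping genome-start
coordinates stable. Ties between equally long repeats prefer the rightmost
match in `G_b`. For exact terminal repeats the trim is exact because the
repeat extension is blocked by the contig boundaries on both sides.

A known confusion, inherited from the coverage-uniformity framework
itself: a linear phage with genuine terminal repeats is indistinguishable
from a circular genome here and will be "circularised". The detector also
fires on long interspersed repeats that happen to cover the probe window
(e.g. tandem arrays) — in the pipeline this is harmless and acts as the
repeat guard that stops unbounded extension.

## Extension mechanics

Recruitment and assembly are deliberately simple and deterministic:

* a read (or its reverse complement) is recruited when it shares ≥ 3
  21-mers with either edge; its mate is always recruited with it;
* the greedy walk repeatedly appends the overhang of the candidate with
  the longest suffix–prefix overlap (≥ 30 bp, ≤ 2% mismatches); candidates
  are found via their first 21-mer, so a read with an error in its first
  21 bases cannot seed a join (it can still be spanned by others);
* equal-length overlaps that disagree on the next base stop that side for
  the round (branch conservatism); agreeing ties resolve to the
  lexicographically smallest read id, making runs reproducible;
* a revisited terminal k-mer stops the walk (cycle guard for repeats);
* growth per side per round is additionally capped (7.5 kb) as a safety
  net.

Mate rescue determines the per-round reach: reads overlapping the edge
reach about one read length outward, and their mates extend the chain by
roughly `insert − read_length` further. For the chain to stay connected,
consecutive recruited reads must overlap by ≥ 30 bp, which requires the
insert to be at most about `edge + 2 * read_length − min_overlap`
(~625 bp at the defaults). This is also why `trim_and_retry()` can work at
all: an accepted trim `t` must be repaid with interest by a *single*
round, i.e. one round must add more than `2t` bp.

## The simulator

`sim_config()` defaults describe the study conditions the test-suite runs
under: uniform i.i.d. genomes, 150 bp reads at 30× coverage, substitution
errors at 1% (0 where a test needs exact arithmetic), paired ends from a
600 ± 60 bp insert with the inner mate reverse-complemented, uniform
fragment starts that wrap the origin for circular genomes. The insert
default was chosen from the chain-connectivity argument above: 600 bp
maximises one-round reach (measured ≈ 640 bp/side) while staying within a
realistic Illumina library range; at 800 bp the mate block detaches from
the edge and reach collapses.

What the simulator does **not** emulate — and what passing tests therefore
do not demonstrate — includes: GC-dependent coverage bias (the audit would
flag biased-but-correct regions, a limitation of the coverage-uniformity
assumption itself), indel sequencing errors (the polisher's indel repair
is exercised by editing the contig against error-free reads instead),
quality-score variation, strain mixtures, and real repeat structure beyond
the constructed tandem arrays.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  inclusive only in prose reports. BED output is 0-based half-open as the
  format requires.
* `N` is accepted in input sequences but never seeds k-mer matches or
  alignments.
* Contigs shorter than `3 * read_length` are declined by the circularity
  check with a warning (not an error); contigs shorter than two edge
  lengths split into two half-contig edges.
* A whole-contig-suspicious audit aborts the run and returns the input
  unchanged with stop reason `whole_contig_suspicious`.
* Placement accepts a read at the modal probe offset when ≥ 2 probes
  agree and the clipped overlap (≥ 30 bp) has ≤ 10% mismatches; reads
  whose two half-reads vote for offsets differing by ≤ 10 bp are the
  indel evidence for polishing.
* A polishing indel is applied only when supported by ≥ `min_depth` reads
  and by ≥ `min_majority` of reads crossing the breakpoint, where the
  opposing set counts only reads that align *mismatch-free* across the
  breakpoint window — if the indel is real no read can do so, which keeps
  partially misplaced reads (indel near a read end) from vetoing the
  repair.
* The iteration log records exactly one terminal stop reason:
  `circular`, `no_growth_after_trim`, `max_iterations` or
  `whole_contig_suspicious`.

## Problem sizes in the shipped checks

The package's own validation (testthat suite plus
`scripts/acceptance.R`) runs entirely on simulated data: 30 kb hosts with
8 kb zero-support inserts at 30×, 40% fragments of 30 kb circular genomes,
100 + 100 random/terminal-redundant sequences of 10–100 kb for the
circularity detector, 500 random depth profiles up to 50 kb against a
brute-force oracle, and 10 kb tandem-repeat genomes for loop safety.
These sizes were chosen as the smallest at which every mechanism
(mate-rescue reach, percentile ties, wrap-around closure) operates exactly
as at full scale.

## Known limitations

* Coverage uniformity is a proxy: regions of genuinely uneven coverage
  (GC bias, amplicon enrichment) can be discarded as chimeric.
* Linear phages with terminal repeats are reported circular.
* The polisher uses unweighted base counts over a depth floor — no
  mapping-quality or proper-pair weighting — and does not reassemble
  discordant regions; indels longer than `max_indel_len` are left to the
  trim/extension machinery.
* Only the dominant path is assembled at branches; the pipeline recovers
  one strain, never a mixture.
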