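---
title: "Conservative De Bruijn graph assembly with conskex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservative De Bruijn graph assembly with conskex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conskex)
```

## The problem and the design stance

Applications that track bacterial pathogens by a handful of variants per
genome need assemblies whose *base-level* accuracy is nearly perfect;
contiguity is secondary.  Illumina read sets complicate this in two specific
ways: systematic errors concentrated on one sequencing strand, and low-level
carryover contamination — reads from an earlier run's almost-identical
sample mixed in at a few percent of the main coverage.

`conskex` assembles short reads through De Bruijn graphs at an ascending
ladder of k-mer sizes and takes the conservative side of every decision: a
contig is extended by one base only when that extension is unambiguous
after a cascade of filters, and any ambiguity that survives the cascade
produces a contig *break*, never a guess.  The distinguishing mechanism is
the final stage: paired reads not yet absorbed into contigs are connected
through the graph into insert-sized fragments, and three further iterations
run with k-mer sizes *longer than the mates* (up to the insert size), which
resolves repeats that are longer than a mate but shorter than the insert —
a region ordinary mate-length k-mers cannot bridge.

## The pipeline

1. **Read trimming.**  A 19-mer present in at least `v_f` (default 0.05) of
   mates, in either orientation, is *suspect* — genomic 19-mers cannot
   reach 5% per-read presence in any realistic library, so suspects are
   adapter or vector signal.  Each mate is clipped at its first suspect
   window; everything from the suspect k-mer onward is removed.  Presence
   is counted per read, not per occurrence, because adapter contamination
   is a per-read phenomenon.

2. **Parameter detection.**  The spectrum of K_min-mers (K_min default 21)
   yields a genome-size estimate G (see below), and with T the total
   trimmed read length the count thresholds scale with coverage:
   `C_min = max(2, floor(T/(50 G)))` (k-mers below it are ignored) and
   `C_max = max(10, floor(T/(10 G)))` (the average count the largest k-mer
   size must still achieve).  K_max starts at the mean mate length A and
   steps down by `floor(A/25)` until the mean k-mer count reaches C_max.
   If K_max exceeds 1.5 K_min, S (default 11) sizes are spread evenly from
   K_min to K_max, interior values rounded to the nearest odd integer (ties
   to the lower odd — a rounding direction the even spread does not dictate,
   fixed here for determinism); otherwise only K_min is used.  For paired
   input the insert I is the median length of fragments obtained by
   connecting a seeded sample of up to 10,000 pairs at K_min; `3 I` bounds
   any fragment considered later, and the three long k-mer sizes are
   `1.25 K_max`, `(1.25 K_max + I)/2` and `I`, odd-rounded and capped at I.

3. **Assembly at one k.**  All k-mers with count at least C_min form the
   graph, with separate plus- and minus-strand counts attributed to the
   canonical form (the lexicographic minimum of a window and its reverse
   complement; self-complementary windows count as plus).  Contigs from the
   previous iteration claim their k-mers and grow at the ends; new contigs
   seed from every unclaimed k-mer with count above the iteration's valley,
   in ascending canonical order.  One extension step applies, in order:
   * **count filter** — candidates below `ext_frac` (default 0.1) of the
     strongest candidate are noise and are dropped (boundary kept);
   * **strand filter** — if any surviving candidate has at least
     `balance_frac` (default 0.25) of its counts on the minor strand, the
     candidates that are predominately single-stranded are dropped.  0.25
     means a 3:1 skew still passes but 4:1 does not; behavior at genome
     scale is insensitive to the exact cut because genuine k-mers at
     usable coverage are close to balanced while strand-specific artifacts
     are extreme;
   * **bounded path exploration** — if several candidates remain, each is
     walked forward up to `max(100, k)` steps under the same two filters; a
     walk that dies at a dead end eliminates its candidate, a walk that
     reaches the cap (or itself forks: ambiguity is not evidence) survives.
     Exactly one survivor resolves the fork; otherwise the contig breaks;
   * **bidirectional verification** — the chosen k-mer's own backward
     extension, through the same cascade, must reproduce the current k-mer;
     convergence points (two balanced in-edges) therefore stop extension
     from either side.
   When an extension stops at a dead end or break, the last k−1 bases of
   that end are removed: they are exactly the bases not yet confirmed by a
   k-mer that was verified in both directions.  Fresh contigs shorter than
   k after trimming are dropped (an isolated seed k-mer disappears);
   contigs carried over from earlier iterations only ever trim bases they
   gained this iteration, so they never shrink.

4. **Marking reads as used.**  After each iteration a read with a k-mer
   deeper than the buffer zone `M = I + 50 + K_max` inside a contig is
   retired: it can contribute nothing new.  Reads near contig ends (within
   M) remain available — they are precisely the reads that may later span
   a junction.  Circular contigs retire every matching read.

5. **Connecting pairs and long-k iterations.**  Pairs still available are
   mapped onto the contigs with K_min-mers; a pair landing inside one
   contig within `3 I` is replaced by the contig substring spanning it,
   and the rest are connected by exhaustive path enumeration between the
   mate anchor k-mers (count floor C_min only — conservatism here comes
   from the uniqueness requirement, not from filtering).  The search runs
   from both ends; success requires exactly one path in each direction and
   agreement between the two.  Mates overlapping by at least k are placed
   directly.  The fragment store then drives the three long-k iterations
   exactly like ordinary reads.

6. **Canonical output.**  Linear contigs keep the orientation whose first
   K_min-mer is lexicographically smaller; circular contigs are rotated to
   start at the smallest K_min-mer over both strands and all rotations;
   contigs sort alphabetically and are named `Contig_N_C` (`_Circ` for
   circular), with C the mean K_min-mer count over the full trimmed read
   set, one decimal place.  Contigs shorter than `min_contig` (default
   200 bp) are dropped from the final output: fragments that short carry
   no reliable information and are where residual contaminant sequence
   concentrates (see below).

## Spectrum peak and valley

The k-mer spectrum of a real read set has a large error/noise mode at very
low counts, the genomic coverage mode, and sparse high-count modes from
repeats and plasmids.  `detect_peak()` scans the multiplicities of the
counts actually present and finds the first rise — the end of the noise
downslope.  The **main peak** is the count with the largest raw multiplicity
above that point; raw, because a window-5 moving average (used elsewhere)
smears the tail of the noise slope into a shoulder that can out-weigh a
sparse genuine mode.  The **valley** is the largest count below the peak at
the minimal smoothed multiplicity: the trough between the genomic mode and
whatever sits below it, taken on the side nearest the peak so that an
entire low-count mode stays below it.  Only k-mers with count above
the valley may seed contigs.  This placement matters for contamination: a
contaminant at, say, 15x forms its own mode well below the 60x genomic
mode, and a valley at the trough between them keeps contaminant k-mers out
of the seed set at every k of the ladder.  When the multiplicities never
rise, no coverage mode is distinguishable; the peak is reported absent, the
valley is zero, and 80% of the distinct k-mers serves as the genome-size
estimate (the substrings sets below are exactly this case — every k-mer has
the same count).

```{r peak-example}
bins <- data.frame(count = c(1, 2, 3, 28, 30, 32),
                   n_kmers = c(1000, 400, 50, 90, 120, 80))
detect_peak(bins)
```

## Determinism

Identical input must give byte-identical output however the work is
scheduled.  Three mechanisms guarantee it.  Counting partitions (the
`batches` argument) are disjoint by a k-mer hash and merge into one sorted
array.  Seeding order may be permuted (the `partitions` argument emulates a
parallel schedule); extensions that run into a k-mer already claimed by
another contig simply stop, and a connector pass afterwards re-applies the
extension test at every such seam, merging contigs end-to-end and
recognizing self-closure as circularity — so the final contig set is the
set of maximal unambiguous paths, which is a property of the graph, not of
the schedule.  For the same reason the filter cascade and the fork-walks
consult only k-mer *counts*, never the (schedule-dependent) claimed flags.
Finally, canonical orientation, canonical rotation of circular contigs and
alphabetical sorting erase any remaining order dependence.  The only random
number stream, the insert-size sample, is seeded (`seed` argument, logged
with the parameters).

## Synthetic test sets and what they do not show

`gen_substrings(genome, K)` emits one error-free read per genome position —
every length-K window, wrapping around for circular genomes so per-base
coverage is exactly K — with reads at even (0-based) positions reverse
complemented so both strands are seen.  `gen_contamination()` emits exact
300 bp fragments as 2x150 bp error-free pairs at 60x, plus pairs from a
copy of the genome with a random 0.1% of positions substituted, at 0–15x;
the mutant copy depends only on the seed, so a coverage sweep uses one
contaminant.  These are the two stress tests a conservative assembler must
pass: coverage/read-length scaling without errors, and carryover
contamination.

They deliberately do **not** emulate sequencing errors, quality-value
structure, coverage bias, indels, or real adapter chemistry.  Passing them
shows that the graph machinery, the filters and the contamination handling
behave as designed — not that error-laden real libraries will assemble
with the same statistics.  The strand filter, in particular, is exercised
only lightly (simulated data is strand-balanced), and is therefore also
unit-tested directly with constructed counts.

On these fixtures the expected behavior, verified by the test suite, is:
substrings sets reassemble the genome exactly (zero mismatches, zero
misassemblies at every K); contamination leaves accuracy intact (0
mismatches/100 kb clean, at most 1 at any level) while contiguity degrades
from about 9x upward, where contaminant k-mer counts clear the `ext_frac`
noise threshold at forks and force breaks.  Isolated contaminant mutations
cannot enter contigs at all: the mutant branch either fails the count
filter (low contamination) or forces a break (high contamination), and a
contig seeded inside a mutant region is boxed in by convergence-point
verification failures and falls below the length floors.  Two contaminant
mutations closer than a mate length can produce a mutant fragment longer
than k; the 200 bp output floor and the evaluator's conventional 500 bp
floor remove these — the same floors under which assemblies of this kind
are conventionally reported and scored.

## The evaluator

`evaluate_assembly()` is a deliberately simple, deterministic scorer for
indel-free simulated data, not a general aligner: exact 21-mer seed matches
between contig and reference are grouped per strand and diagonal into
gapless blocks, extended while bases match; a greedy longest-first chain
covers the contig.  A junction between chained blocks with inconsistent
strand, inconsistent reference order, or a reference gap above 1 kb (the
conventional "extensive misassembly" distance) counts as a misassembly.
Mismatches are substitutions inside aligned blocks, normalized per 100 kb
of aligned length; the length-deviation statistic is
`L_R + L_A − 2 C_RA` (reference length plus assembly length minus twice
the aligned length).  Circular references are doubled so wraparound
alignments stay contiguous, and alignment is end-gap free, so the k−1
end-trimming of contigs is never miscounted as error.

## Numerical and degenerate-input choices

* Integer formulas use `floor` (C_min, C_max, the A/25 step); evenly spread
  ladder values round half-up before odd-rounding.
* Count-filter and strand-filter boundaries are kept (`>=` with a 1e-9
  epsilon so 10 of 100 survives `ext_frac = 0.1` despite floating point).
* The pair-connection search is budgeted (`path_cap` times the maximal
  insert in explored steps); exceeding the budget is a connection *failure*,
  never a partial answer.  The insert estimator uses a tighter budget and a
  1200 bp exploration limit — inserts beyond that should be supplied with
  `insert_size`.
* Reads containing N are kept; windows containing N are never generated.
  Reads shorter than the current k contribute nothing at that k.
* An empty read store, a store trimmed to nothing, and a k exceeding every
  read length are hard errors or warned empty results, not silent successes.
* Ties everywhere (orientation, rotation, sorting, seeding) break by
  byte-wise lexicographic order, locale-independent.

## Problem sizes used by the test suite

Unit fixtures are hundreds of bases to a few kilobases.  The end-to-end
checks use a 50 kb circular genome for the substrings sets (K = 22, 60,
100, 150), a 100 kb circular genome for the six-level contamination sweep,
a 20 kb fixture for byte-identity across repeated runs and worker
partitionings, and a 9.4 kb three-segment genome with a 200 bp duplicated
repeat for the long-k resolution property.  These sizes exercise every
code path (including circularity, retirement, connection and long-k
merging) while keeping the full suite comfortably within a coffee break;
the mechanisms do not change with scale, only the constants do.

## Known limitations

* Single-end or high-error (long-read) data assembles but loses the
  pair-connection stage entirely; the conservative filters will fragment
  high-error data severely by design.
* The evaluator assumes indel-free contigs; real-data evaluation should
  use a full-featured external tool.
* Scaffolding, gap filling and explicit error correction are out of scope;
  ambiguity is reported as a break, never bridged with Ns.
* The census threshold for adapter trimming (5% of reads) can flag genuine
  repeats on genomes smaller than ~10 kb at high coverage — a regime real
  libraries never occupy, but worth knowing when building toy fixtures.
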