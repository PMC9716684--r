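---
title: "Reconstructing and evaluating MAGs from long reads alone: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and evaluating MAGs from long reads alone: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanomag)
```

## The problem

Metagenome-assembled genomes (MAGs) built purely from Nanopore long reads
can reach reference quality without short-read polishing, provided three
things are handled carefully: which reads enter the assembly (quality-aware
filtering), which reads polish which genome (genome-resolved read
partitioning), and how the per-genome consensus is formed (iterative
pileup polishing).  `nanomag` implements that reconstruction path end to
end, together with the evaluation battery used to decide whether the
result deserves to be called a MAG at all: single-copy-marker completeness
and contamination, contiguity, indel rates against a reference,
homopolymer confusion, IDEEL full-length protein fractions, quality
tiering, and prophage activity calling from coverage.  Every stage is
exercisable at desk scale through a built-in community simulator that
emits complete ground truth.

## Read filtering

Nanopore base qualities encode per-base error probabilities.  The
*predicted mean read identity* is

$$\mathrm{id}(r) = 100\left(1 - \frac{1}{L}\sum_{i=1}^{L} 10^{-Q_i/10}\right),$$

the arithmetic mean of error probabilities converted back at the end.
This is deliberately *not* a mean in Phred space: on mixed-quality reads
the two differ materially, and the error-probability mean is the
convention of the long-read filtering tools this stage mirrors.
`filter_reads()` keeps a read iff its length is at least `min_length`
(default 1000) and its predicted identity is at least `min_identity`
(default 90, the QA90 working point; 80 and 95 give QA80/QA95).  Both
comparisons are inclusive; the source descriptions of this rule are
ambiguous between "at least" and "above", and we chose `>=` and document
it here.

## Alignment

`build_index()`/`map_reads()` provide a self-contained k-mer-seeded
banded aligner so the pipeline needs no external mapper at desk scale;
externally produced SAM/PAF is accepted everywhere in its place and takes
precedence when supplied.  Seeds (k = 15, target stride w = 5, both
strands via reverse-complement lookup) are grouped per (target, strand),
clustered by diagonal within a tolerance of `band_fraction` times the
read length (default 0.15, floor 64), and the longest colinear subset of
each cluster is extended with a banded unit-cost edit-distance DP over
the chained span plus flanks, with free end gaps on the target side.
Affine gap costs are out of scope: at these error rates unit costs
recover the same intervals.

One numerical choice deserves a note: the *chaining* tolerance is
`band_fraction * read_length`, but the DP band itself is sized from the
chain's observed diagonal drift (plus 64 columns and 2% of the read
length of slack), capped at the chaining tolerance.  A fixed 15% band
would spend roughly seven times the cells for identical output at the
simulated error ceiling; the seeded benchmark (95% of 5%-error reads
mapped within +-50 bases of their true origin) is part of the test suite
and holds under the adaptive band.

Identity is always reported in the BLAST convention — matches over all
alignment columns including indel columns — and CIGARs use `=`/`X`
resolved ops.  `M` is accepted on input, resolved against sequences when
they are available, and otherwise treated as a match for length
bookkeeping only.  All internal coordinates are 0-based half-open; SAM
converts at the boundary, and reverse-strand CIGARs always describe the
reverse-complemented read against the forward target while
`query_start`/`query_end` stay on the original read.

## Read-to-bin partitioning

`assign_reads()` implements the genome-resolved detangling rule: a read
joins a bin's cluster iff its identity against that bin is at least 90%
and at least 90% of the read aligns to the bin (both inclusive,
both configurable).  Two readings of "90% coverage" are possible —
fraction of the read aligned, or breadth of the bin covered — and only
the per-read reading yields a per-read membership rule, so that is what
is implemented.  Identity across a read's multiple alignments to one bin
is length-weighted (sum of matches over sum of columns), which is stable
when long reads split across contig ends; the aligned fraction is the
query-interval union, so split and secondary alignments cannot
double-count.  A read may enter several clusters (unique assignment was
never stipulated, and per-bin polishing is independent); `unique_best =
TRUE` restricts each read to its best bin by identity, then fraction,
then bin id.

## Polishing

`polish_bin()` iterates align → pileup → consensus on each bin with its
own cluster only.  The consensus is a transparent pileup majority: per
column, the argmax over {A, C, G, T, deletion} with ties broken toward
the draft base, then `A < C < G < T`, then deletion (a deletion must
strictly beat every base); per junction, the plurality inserted string is
emitted iff it reaches half the spanning reads.  Columns and junctions
spanned by fewer than `min_depth = 2` reads keep the draft — below that
depth a single noisy read would otherwise rewrite the genome.  Insertions
longer than 50 bases are never emitted (a guard against chimeric read
artifacts), and `N` is never emitted at a covered column nor counted as a
vote.

This single polisher stands in for the two-stage POA + neural polishing
used by production pipelines; the fidelity target is behavioral (error
removal at coverage), not algorithmic.  The default is **2 rounds with a
convergence stop** (a round that changes nothing ends the loop): the
recommended regime is one round of each polisher and additional
long-read rounds have been observed to degrade quality slightly, so we
cap rather than iterate to a fixed point.  Round 1 may reuse externally
supplied alignments (the pipeline reuses the partitioning alignments);
later rounds always realign because coordinates shift.  Per-bin
independence is a contract, not an accident: the output for a bin is a
pure function of that bin's draft and cluster, which the test suite
checks by permuting cluster order.

## Evaluation

* **Completeness / contamination** use a transparent set-based formula on
  explicit detector markers: completeness is the percentage of markers
  present at least once (forward or reverse complement, exact match,
  overlaps counted); contamination is the percentage of extra copies.
  This is the leading-order behavior of lineage-marker appraisal without
  the database dependence.  MAG retention is strict: completeness
  **above** 50% and contamination **below** 10%.
* **Tiers**: `high` needs completeness > 90, contamination < 5,
  full-length 5S/16S/23S and >= 18 tRNAs (annotation flags are inputs;
  rRNA/tRNA detection is out of scope and missing flags cap the tier at
  `medium` with a warning); `medium` is anything else retained.
* **Indels** are counted as events (one multi-base gap = one event) per
  100 kb of aligned reference, with the mismatch analogue alongside.
* **Homopolymer confusion**: for every reference run of length >=
  `min_run = 3` fully inside an alignment, the observed length is the
  count of query bases equal to the run base over the run's columns plus
  pure-base insertions at the run's internal and two boundary junctions;
  one tally per (run, spanning alignment); true lengths pool at `L_max =
  10`.  The boundary-junction rule is our stated choice — tools differ
  and none document it precisely; keeping boundary insertions inside the
  run makes an extension of the run by one base land in the `t, t+1`
  cell, which is what the confusion matrix is for.
* **IDEEL**: a protein is full-length iff its predicted length strictly
  exceeds 95% of its best database hit's length; the score is the
  full-length fraction.  Protein prediction and the database search are
  consumed as a two-column length table — the reference database is a
  100-GB-class dependency that has no place inside this package.
* **Medians** use `stats::median` (mean-of-middles on even counts),
  disclosed because run-level headline numbers are medians.

Assembly-to-truth alignment for the indel and identity measures cuts
contigs into 50 kb chunks and maps them with a narrow band (2% of chunk
length): a polished assembly sits within a fraction of a percent of its
reference, so a narrow band suffices and bounds DP memory.

## Prophage activity

Prophage coordinates are inputs (discovery is out of scope).  Regions
strictly longer than 1 kb are scored by comparing mean read depth inside
the region against the host contig with the region plus a 500-base buffer
excluded.  A call is `active` when the depth ratio reaches 1.65, Cohen's
d (population variances, floored at 0.25 so uniform synthetic coverage
keeps d finite) reaches 0.70, and host depth is at least 1; zero host
depth or arrays shorter than 100 positions give `not_determined`.  The
thresholds mirror the published defaults of the standard coverage-ratio
activity caller and are fully configurable; depth is depth, so long or
short reads both work as the source.

## The simulator and what it does (not) show

`mock_community()` + `simulate_reads()` generate the study conditions:

* **Genomes**: i.i.d. GC-weighted bases with a geometric run-extension
  knob (`hp_enrichment`, default 0.02 in the pipeline defaults) so that
  homopolymer runs long enough to be interesting actually occur.
* **Abundances**: even by default for controlled experiments;
  `log_spread_abundance()` reproduces the staggered mock-community shape
  (members spanning several orders of magnitude down to 1e-4).
* **Read lengths**: lognormal (mu 8.45, sigma 0.55), truncated at 1 kb
  and the genome length, giving a read N50 near 6 kb — the scale of the
  libraries this pipeline targets.
* **Errors**: per-base substitution/insertion/deletion plus a per-run
  homopolymer component — every run of length >= `hp_min` is contracted
  or extended by exactly one base with probabilities `p_hp_contract` /
  `p_hp_extend`.  At most one length error per run keeps the true CIGAR
  well-defined while reproducing the dominant Nanopore error mode.
  Presets: `kit9-like` (4.5% total, heavier homopolymer error) and
  `q20-like` (2.0%) are calibrations anchored to the median accuracies
  of the two chemistries, not measured profiles.
* **Read-level variation**: a lognormal, mean-1 multiplier
  (`read_level_sd`, default 0.3) scales each read's base-level error
  rates.  Without it every read has the same quality and predicted
  identity carries no information about mapped identity; with it the
  predicted-vs-mapped relationship (and its Spearman correlation) exists
  to be tested.
* **Qualities**: per-base Phred from the base's applicable error
  probability with uniform integer jitter on {-2..2}, clamped to
  [2, 41] — the jitter prevents a degenerate exact quality-to-error
  inversion in filter tests.
* **Truth**: read origins, exact CIGARs from the applied edit script
  (validated against read and genome in the tests), planted single-copy
  markers, and prophage regions.  Reads from circular genomes may wrap
  the origin; the truth then carries two alignments for the read.
  `coverage_overrides` oversample reads wholly inside a region by a
  given fold — implemented as virtual community members restricted to
  the region with weight `(fold - 1) * region_length / genome_length` —
  which is how an actively replicating prophage's coverage excess is
  emulated.

What the simulator does **not** emulate: chimeric reads and adapters,
signal-level artifacts, basecaller-version effects, strain mixtures,
conserved inter-genome homology (members are independent random
genomes), and real marker genes (markers are unique random tags).  A
passing simulation therefore shows the machinery is correct under the
stated error model, not that any particular real community will yield
the same numbers; cross-genome read stealing in particular is easier
here than between related strains, which is why strain resolution is
explicitly out of scope.

## Determinism and seeds

Every stochastic function takes an explicit integer seed and scopes R's
Mersenne-Twister via `withr::with_seed`, so identical inputs give
byte-identical outputs across platforms.  The pipeline derives
per-component seeds from the single config seed by fixed offsets
(genomes at `seed + 1000 i`, marker planting at `+1000 i + 1`, prophage
at `+77`, read simulation at `+500`).  The end-to-end test runs the
pipeline twice into fresh directories and compares report bytes.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk
scale: a five-genome, 2 Mb, 20X community with ~5% read error for the
end-to-end run; 100 kb / 30X for polish-recovery; ~600 planted runs at
15X for homopolymer recovery; 20 replicates of a 52 kb host at 10X for
prophage activity.  These sizes were chosen as the smallest at which the
binomial noise on each measured quantity is comfortably inside the
asserted tolerance.

## Known limitations

* The aligner is a desk-scale stand-in: no minimizers, no SIMD, no
  split/chimeric alignment; genomes beyond a few tens of Mb per index
  deserve a production mapper (whose SAM/PAF drops straight in).
* The polisher is a pileup majority; it will not out-resolve a neural
  polisher on systematic homopolymer bias, which is visible in the
  residual homopolymer-masked vs overall identity gap.
* Completeness from exact-match tags is blind to partially assembled
  markers; real marker appraisal degrades more gracefully.
* Binning itself, assembly, rRNA/tRNA annotation, taxonomy and prophage
  discovery are consumed as inputs, never computed.
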