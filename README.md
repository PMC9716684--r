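# nanomag

Reconstruction and evaluation of metagenome-assembled genomes (MAGs)
from Nanopore long reads **alone** — no short-read polishing step.

`nanomag` is for microbiome researchers who want the long-read-only MAG
reconstruction path as a transparent, testable toolchain: quality-aware
read filtering, genome-resolved read partitioning, iterative per-bin
consensus polishing, and the genome-accuracy battery used to decide what
counts as a reference-quality MAG.  A built-in mock-community simulator
with complete ground truth makes every stage runnable and checkable on a
laptop.

## The method

Given filtered long reads and draft genome bins (from any
assembler/binner), the pipeline:

1. **Filters reads** on length ≥ 1 kb and *predicted mean read identity*
   `100·(1 − mean(10^(−Q_i/10)))` ≥ 90 (the QA90 rule; QA80/QA95 are one
   flag away).
2. **Partitions reads into per-bin clusters**: a read joins a bin iff its
   BLAST-convention identity to the bin is ≥ 90% *and* ≥ 90% of the read
   aligns (length-weighted identity over split alignments, query-interval
   union for the aligned fraction).
3. **Polishes each bin independently** from its own cluster: up to two
   rounds of align → pileup → majority consensus with a convergence stop,
   per-column argmax over {A,C,G,T,deletion} (ties: draft, then A<C<G<T,
   then deletion), junction insertions at ≥ 50% of spanning reads,
   `min_depth = 2` below which the draft is trusted.
4. **Evaluates** the result: single-copy-marker completeness /
   contamination (retention: completeness > 50%, contamination < 10%),
   N50/contiguity, indel events per 100 kb and identity vs a reference,
   homopolymer true-vs-observed confusion matrices, IDEEL full-length
   protein fraction (`query > 0.95 × best hit`, strict), and MIMAG-style
   quality tiers.
5. **Calls prophage activity** from coverage: a prophage interval (> 1 kb)
   is `active` when its depth is ≥ 1.65× the host's with Cohen's d ≥ 0.70.

A k-mer-seeded banded aligner is built in so nothing external is needed
at desk scale; minimap2-style SAM/PAF is accepted in its place anywhere.

## Worked example

Simulate a five-genome mock community (2 Mb total, 20X, ~5% read error,
one coverage-boosted prophage) and run the whole pipeline:

```r
library(nanomag)
res <- run_pipeline(list(
  out_dir = "e2e", seed = 1,
  simulate = list(n_genomes = 5, genome_length = 400000,
                  total_bases = 4e7,
                  model = error_model(0.05/3, 0.05/3, 0.05/3),
                  prophage = list(length = 15000, fold = 3))))
res$report[, c("bin_id", "completeness", "contamination", "n50",
               "coverage", "indels_per_100kb", "identity")]
```

```
     bin_id completeness contamination    n50 coverage indels_per_100kb identity
1 genome_01          100             0 415012 20.75025         2.891566 99.99687
2 genome_02          100             0 400019 18.47748         5.750000 99.99425
3 genome_03          100             0 400006 19.49714         1.500000 99.99850
4 genome_04          100             0 400021 19.71605         7.750000 99.99200
5 genome_05          100             0 400011 18.77258         2.750000 99.99725
```

All five planted genomes come back as retained MAGs at 100% marker
completeness and zero contamination; after two polishing rounds the
consensus sits at ~99.99% identity to the truth with single-digit indel
events per 100 kb.  The planted prophage is recovered as active:

```r
res$prophage_calls
```

```
        name contig_id start    end prophage_depth host_depth    ratio effect_size verdict
1 prophage_1 genome_01 2e+05 215000        55.3748   19.45454 2.846369    3.034464  active
```

— its 3-fold simulated coverage excess yields a depth ratio of 2.85 and
an effect size of 3.03, both clear of the 1.65 / 0.70 thresholds.  Each
stage also writes its artifacts (`kept.fastq`, `mapped.paf`,
`clusters.tsv`, `polished/`, `report.tsv`, `summary.json`,
`prophage_calls.tsv`) under `out_dir`.

The same stages are scriptable from a shell via the thin CLI installed at
`exec/nanomag` (`simulate`, `filter`, `map`, `partition`, `polish`,
`evaluate`, `prophage`, `run`).

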