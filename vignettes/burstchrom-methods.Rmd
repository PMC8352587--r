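---
title: "Models and methods behind burstchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind burstchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological setting

In early *Drosophila* embryos, transposable elements (TEs) escape silencing
for a short developmental window after zygotic genome activation: one
dominant family bursts to roughly 1.7% of the transcriptome — more than 70%
of all TE-derived reads — before being shut down again. Silencing is guided
by maternally deposited Piwi loaded with 23–28 nt, antisense-biased piRNAs,
and leaves a repressive H3K9me3 footprint at euchromatic TE insertions. Two
features of that footprint carry mechanistic information: it *lags* the
expression peak by about one developmental time interval, and it is *skewed
downstream* of each element in its direction of transcription, as expected
for co-transcriptional silencing of nascent transcripts.

burstchrom packages the computational side of such a study — read
assignment, insertion discovery, chromatin quantification, differential
testing, small-RNA processing — together with a synthetic-data generator
that emits every library type with full ground truth, so each stage can be
validated end to end without any external data.

## The synthetic-data generator

`sim_config()` fixes the study conditions. The defaults are:

* **Genome**: two 500 kb euchromatic chromosomes, a 100 kb constitutive
  heterochromatin block, and a 50 kb chr4-like chromosome, all i.i.d.
  nucleotides at GC 0.42. This toy scale keeps every test in minutes while
  preserving the structures the methods rely on (unique k-mers, separable
  compartments).
* **TE families**: three consensus sequences of 2,000/1,500/1,200 bp. Thirty
  insertions (18/7/5 per family) are planted uniformly in euchromatin with a
  2 kb minimum junction spacing and random strand; the "sample" genome
  splices the full consensus at each junction with no target-site
  duplication, while the "reference" genome lacks it. Sparse insertions
  (~1 per 30 kb) mirror the real situation in which insertion-centred 10 kb
  windows rarely overlap a neighbour; the insertion-calling analyses use a
  denser 100-insertion configuration, where kernel overlap is irrelevant.
* **Expression**: per-family transcriptome fractions over six timepoints
  (hours after egg laying), with the dominant family peaking at 0.017 at
  4–6 h. Background "genic" reads are drawn uniformly from euchromatic
  *reference* sequence — i.e. from everything that is not a TE copy — since
  family-level quantification needs no gene models.
* **ChIP kernel**: IP read density around a planted insertion is
  `1 + lag(t) * (E0 - 1) * exp(-d / lambda_side)`, with `E0 = 8`,
  `lambda = 750` bp upstream and `lambda * s` downstream (`s = 3`), `d = 0`
  inside the element. `lag(t)` in [0, 1] scales the amplitude per timepoint
  and peaks one interval after the expression peak. Excess terms add across
  insertions; for an isolated insertion the closed form is exact, which is
  what the kernel-recovery tests check. The heterochromatin block and the
  chr4-like chromosome receive constant 8- and 5-fold enrichments.
  Choosing `lag` as a multiplier on `E0 - 1` (rather than on `E0`) makes the
  kernel collapse exactly to the flat background at `lag = 0` and at
  `E0 = 1`, the two degenerate controls.
* **WGS**: Poisson fragment count at 30x mean coverage, Gaussian fragment
  lengths (500 ± 60 bp), 150 bp mates in FR orientation. The insert-size SD
  and error model are free parameters of the design; error-free defaults
  make truth comparisons exact, and a per-base substitution rate is
  available where robustness matters.
* **Small RNA**: reads are `4 random nt + insert + 4 random nt + adapter`
  with insert lengths on 19–31 nt (mode 26), 80% antisense, and per-family
  fractions 0.16/0.09/0.75 — the dominant family's ~16% and the second
  family's ~9% share of antisense piRNAs are the profile the embryonic Piwi
  analysis reports.

One master seed expands into per-library child seeds through a fixed affine
map (`child_seed()`), so adding a library never perturbs the reads of
another, and identical configurations are byte-identical across runs.

What the generator does *not* emulate: sequencing quality variation, PCR
duplicates, GC bias, truncated or nested insertions, target-site
duplications, spliced transcripts, and mappability structure of a real
genome. Passing tests therefore demonstrate correctness of the *algorithms*
under their stated models, not robustness to every artefact of real
libraries.

## Read assignment (two-tier policy)

Real pipelines map to the TE consensus library first (randomly allocating
multimappers), then map the remainder uniquely to the genome. `build_index()`
and `assign_reads()` reproduce that policy with an exact k-mer seed index
(default `k = 21`, two seeds per read so a single substitution cannot hide a
hit) and full-read verification with at most `max_mismatches = 2`
substitutions:

1. any TE-consensus hit at the read's best mismatch count assigns the read
   to a family; ties among equal-best families are broken by one uniform
   draw per read from a seeded stream that advances in input order, so the
   full assignment vector is reproducible and only tie-breaks depend on the
   seed;
2. otherwise a read with exactly one best genome locus is assigned uniquely;
3. everything else — including genome multimappers — is discarded.

The rpm denominator is the number of TE plus genome assigned reads, so
`rpm = count * 1e6 / library_total` and rpm sums to exactly 1e6 over any
complete feature partition. A minimal SAM-subset reader
(`read_sam_subset()`, MAPQ-255 uniqueness convention, 1-based to 0-based
conversion) lets pre-aligned data bypass the built-in aligner.

The surrogate aligner makes no attempt to reproduce a spliced aligner's
scoring; on synthetic reads that are exact substrings it is lossless, which
is the property the truth-table tests exploit.

## Insertion discovery

Non-reference insertions are visible as read pairs with one genome-unique
mate and one TE mate. `collect_evidence()` anchors each such pair at the
genome mate's innermost coordinate (its end for `+` mates pointing rightward
into the junction, its start for `-` mates), so the innermost left and right
anchors converge on the junction. `cluster_and_call()` single-links anchors
per (chromosome, family) with a gap of `fragment_mean + 3 * fragment_sd`
(all anchors of one insertion fall within about one fragment span) and
retains clusters supported on **both** sides — the 1p1 presence/absence
rule. Directionality is a per-record vote (`left` with a `-` TE mate, or
`right` with a `+` TE mate, votes `+`), majority-decided, `.` on ties.
Insertion frequency estimation and split-read evidence are deliberately out
of scope. `evaluate_calls()` scores greedy 1-to-1 matches within ±50 bp;
on the 100-insertion, 30x error-free design, precision, recall and strand
accuracy all reach 1.0 with a median junction error of a few bp.

## Chromatin signal

`coverage_track()` bins per-base read overlap (default 10 bp bins) and
scales to rpm; mass conservation (`sum(value * bin / 1e6 * library_total) =
mapped bases`) is tested exactly. Windowed IP/input enrichment
(`window_enrichment()`, default non-overlapping 10 kb windows — "sliding"
step is configurable) is `log2((ip + psi) / (input + psi))` with
`psi = 0.5` rpm; `call_euchromatin()` merges sub-threshold runs with the
default `tau = log2(2)`. Because rpm normalisation spreads the IP library's
enrichment mass over the whole genome, absolute window enrichments sit below
the raw kernel folds; the heterochromatin block still separates cleanly from
euchromatin at the 2-fold threshold under the default conditions, and the
threshold is exposed because neither the ratio scale nor the cutoff of the
original annotation is published.

`insertion_matrix()` extracts ±10 kb of track around each junction midpoint
and reverses rows of `-` strand insertions, so column index increases
5'→3'; flipping every strand reverses every row exactly (an involution the
tests assert). `metaprofile()` gives sentinel-masked column statistics;
`asymmetry_score()` is `(mean downstream + psi) / (mean upstream + psi)`,
>1 when the mark trails transcription. Heatmap rows default to genomic
order; the sort key is an argument since "sorted 5' to 3'" admits several
readings.

## Differential binned counts

`bin_counts()` counts each read once, in the 5 kb bin containing its
leftmost position. `size_factors()` is the median-of-ratios estimator,
centred so the median factor is 1 (this makes "one sample doubled" give
factors 1, …, 2, and cancels in every fold-change). `nb_test()` is a
negative-binomial Wald test: per-feature method-of-moments dispersion
pooled across the two groups, then shrunk (weight 0.8) toward the
across-feature mean — with 2–3 replicates the per-feature moment estimate
alone is far too noisy to calibrate anything, and sharing dispersion
information across features is precisely the device of the DESeq2/edgeR
family — floored at 1e-8, delta-method standard error on the log2
fold-change, standard normal reference, BH adjustment over tested features,
all-zero features excluded. The package does not attempt numerical equality
with DESeq2 (no GLM refitting, no fold-change shrinkage, no independent
filtering); it is calibrated by simulation instead: on a 3-vs-3 null with
`mu = 100` and dispersion 0.05 over 5,000 bins the raw-p type-I rate sits
inside the 3-sigma binomial band around 0.05, and a planted two-fold
depletion over 200 bins (among 300 null bins) is detected at `padj < 0.05`
with power above 0.8. Known limitation of the normalisation: when a large
fraction of features changes in one direction, median-of-ratios factors are
biased (the usual majority-unchanged assumption); simulations that generate
counts without library-size effects therefore pass unit size factors
explicitly.

`attribute_bins()` links significant bins to families by interval distance
(boundary-inclusive, default 5 kb); both raw and adjusted p are available
because published "p < 0.05" counts are often ambiguous between the two.

## Small RNA processing

`clip_and_trim()` finds the 3' adapter by a 5 nt exact seed plus
mismatch-tolerant suffix verification (1 per 10 nt), discards reads shorter
than 15 nt after clipping, and trims the 4 random linker nucleotides from
each end; unclipped reads are kept by default, matching the behaviour of the
classic clipping tools. `size_filter()` applies the inclusive 19–31 nt
window (the Piwi-bound mode, 23–28 nt, is recovered as the profile mode
rather than imposed). `orient_and_assign()` reuses the consensus index
(`k = 15`, below the shortest read) with sense/antisense given by the
matched strand, and `antisense_fraction_table()` reports each family's
percentage of all TE-mapping antisense piRNAs.

## End-to-end drivers

`run_timecourse()` reproduces the developmental design: per timepoint it
simulates and assigns RNA and ChIP libraries, quantifies TE fractions,
builds insertion-centred matrices, and summarises the expression peak, the
chromatin peak, their lag (in timepoints), and the median asymmetry.
`run_depletion_comparison()` reproduces the maternal-depletion design: the
treated condition switches the kernel off at the depleted family's
insertions and scales that family's RNA 2.5-fold, then family-level MA
tables, 5 kb bin differential with attribution, and region-level t-tests
(insertion flanks vs heterochromatin block vs chr4-like) are computed with
3 replicates per condition. Both drivers are deterministic given the
pipeline seed and write plain TSV/JSON reports.

## Problem sizes and numerical choices

Tests and the acceptance script run at the generator's default scales
(1.15 Mb genome, 30 planted insertions for chromatin analyses; 1 Mb,
100 insertions, 30x paired-end WGS for insertion calling; 200k RNA reads;
100k ChIP reads per library; 50 seeded reruns for the lag property). The
pseudocounts (`psi = 0.5` rpm for ratios, 0.5 normalised counts in fold
changes) guarantee finiteness at zero coverage; degenerate t-tests report
p = 1 (equal zero-variance means) or p = 0 with a flag; matrix columns are
snapped to the track's bin grid; and clustering ties at exactly `max_gap`
are kept in one cluster (gap strictly greater splits).
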