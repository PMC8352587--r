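# burstchrom

Analysis toolkit for a transient transposon expression burst in early
embryos and the heterochromatin response it triggers — with a built-in
synthetic-data generator so every stage is testable against ground truth.

## The problem

Shortly after zygotic genome activation, *Drosophila* embryos transiently
express transposable elements (TEs): one dominant family peaks at ~1.7% of
the transcriptome (over 70% of all TE-derived reads) before silencing
resumes. Maternally deposited Piwi, loaded with 23–28 nt antisense-biased
piRNAs, converts active insertions into H3K9me3 heterochromatin. Two
signatures identify this as co-transcriptional silencing: the chromatin
response *lags* the expression peak by roughly one developmental interval,
and the repressive mark is *skewed downstream* of each element in its
direction of transcription.

Analysing such a study requires several connected pieces, all provided here
as tidyverse-style functions (data frames in, tibbles out):

* **Read assignment** (`build_index()`, `assign_reads()`): the two-tier
  policy — align to TE consensus sequences first with seeded random
  allocation of multimappers, then uniquely to the genome, discarding
  genome multimappers. Normalisation is reads per million, with
  `rpm = count × 10⁶ / (TE + genome mapped reads)`.
* **Insertion discovery** (`collect_evidence()`, `cluster_and_call()`):
  non-reference TE insertions from discordant WGS read pairs (one mate
  genome-unique, one TE), single-linkage clustering of junction anchors,
  the both-sides "1p1" support filter, and majority-vote directionality.
* **Chromatin signal** (`coverage_track()`, `window_enrichment()`,
  `call_euchromatin()`, `insertion_matrix()`, `metaprofile()`,
  `asymmetry_score()`): 10 bp rpm tracks, 10 kb windowed
  `log2((IP + ψ)/(input + ψ))` enrichment for euchromatin annotation, and
  strand-oriented ±10 kb signal matrices around insertion junctions, with
  the downstream/upstream asymmetry ratio.
* **Differential bins** (`bin_counts()`, `size_factors()`, `nb_test()`,
  `attribute_bins()`): negative-binomial Wald tests on 5 kb binned counts
  (median-of-ratios size factors, moment dispersion shrunk across features,
  Benjamini–Hochberg adjustment) and attribution of significant bins to TE
  families within 5 kb.
* **Small RNA** (`clip_and_trim()`, `size_filter()`, `orient_and_assign()`,
  `antisense_fraction_table()`): adapter clipping, 4 nt linker trimming,
  the inclusive 19–31 nt filter, and per-family antisense piRNA shares.
* **Simulation** (`sim_config()`, `build_genome()`, `simulate_*()`): a toy
  genome with planted insertions and four library types (RNA-seq, ChIP
  IP/input, paired-end WGS, small RNA), each emitting a per-read truth
  table.
* **Drivers** (`run_timecourse()`, `run_depletion_comparison()`): the two
  end-to-end experimental designs on synthetic data.

## Worked example

```r
library(burstchrom)
cfg <- sim_config(master_seed = 7)
genome <- build_genome(cfg)
te_idx  <- build_index(genome$te_seqs,   k = 21)
gen_idx <- build_index(genome$reference, k = 21)

# quantify the burst at its peak timepoint
rna <- simulate_rnaseq(genome, cfg, timepoint = "4-6h", n_reads = 50000, seed = 1)
asn <- assign_reads(rna$reads, te_idx, gen_idx, seed = 2)
tc  <- te_fraction_timecourse(list("4-6h" = rpm_normalize(count_features(asn))))
tc$by_family
#> # A tibble: 3 × 4
#>   timepoint family   pct  rank
#>   <chr>     <chr>  <dbl> <int>
#> 1 4-6h      TE297  0.172     3
#> 2 4-6h      copia  0.352     2
#> 3 4-6h      roo    1.75      1

# rediscover the planted insertions from 30x paired-end WGS
wgs   <- simulate_wgs(genome, cfg, seed = 3)
calls <- call_insertions(wgs, te_idx, gen_idx, max_gap = default_max_gap(cfg))$calls
evaluate_calls(calls, genome$insertions, position_tolerance = 50)
#> # A tibble: 1 × 7
#>   n_calls n_truth n_matched precision recall median_position_error
#>     <int>   <int>     <int>     <dbl>  <dbl>                 <dbl>
#> 1      30      30        30         1      1                     4
#> # ℹ 1 more variable: strand_accuracy <dbl>
```

The family percentages are percent of the whole transcriptome: the dominant
family sits at 1.75% (configured burst 1.7%, binomial sampling noise at
50k reads), holding ~77% of TE reads. All 30 planted insertions are
recovered exactly (precision = recall = 1) with a 4 bp median junction
error.

`autoplot()` methods and `plot_*()` helpers (heatmaps, metaplots, MA plots,
size profiles, time courses) visualise each result type; `tidy()` and
`glance()` methods give broom-style access to fitted differential objects.

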