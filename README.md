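# clipscape

Analysis stack for CLIP-seq studies of nuclear RNA-binding proteins, built on
the Bioconductor ranges infrastructure. It answers three questions about a
crosslinking-immunoprecipitation experiment run against an RNA-seq input:

* **Where does the protein bind?** The genome is dissected into 50-bp
  windows; windows enriched in CLIP over input RPKM
  (RPKM = count x 10^9 / (width x library size)) are merged into binding
  clusters under either published filter variant (pooled: fold > 2 and
  summed reads >= 10; per-replicate: fold > 2 in >= 2 replicates and summed
  reads > 10). Nucleotide resolution comes from crosslink-induced
  deletions: positions with > 5 reads coverage and >= 5% deletion frequency
  are called as crosslink sites, their flanks are scanned for k-mers by
  ZOOPS counting (zero-or-once per sequence), each k-mer is tested per
  replicate with a one-sided Fisher exact test against a position-matched
  background, and replicate p-values are combined by Fisher's method
  (chi-square = -2 sum log p, 2m df).
* **What does it bind?** Reads are categorized by a 12-class priority table
  (rRNA > tRNA > snoRNA > snRNA > miRNA > mRNA exon > mRNA intron > mRNA
  unknown > lincRNA > repeat > antisense mRNA > unannotated), coverage is
  profiled around anchor sets (TSS, poly(A) sites, modification positions)
  in transcription orientation, and pre-mRNA binding is quantified by the
  ratio of exon-intron boundary reads (EI) to exon-exon junction reads
  (EE), compared between CLIP and input with a Student's t-test on
  EI/(EE+EI).
* **What happens without it?** Exon-level differential-expression tables
  over flattened exonic parts (isoform boundaries projected into disjoint
  bins, numbered from the 3' end) feed a Fisher exact test for enrichment
  of DE among last exons, directional up/down summaries, per-position
  log2FC profiles, CDF comparisons (Mann-Whitney U) and cross-condition
  Pearson correlations.

A deterministic simulator (`sim_config()`, `simulate_reference()`,
`simulate_clip_experiment()`, `simulate_exon_de_table()`) generates a small
multi-gene genome, annotation, aligned CLIP/input reads (sorted+indexed BAM
or in-memory) and DE tables with planted ground truth — enriched windows,
crosslink positions carrying a planted motif, a last-exon bias — so the
whole pipeline is testable end to end without any downloads.

## Worked example

```r
library(clipscape)

cfg <- sim_config(seed = 1)             # 12 genes, ~100 kb, 3x50k CLIP + 50k input
ref <- simulate_reference(cfg)
sim <- simulate_clip_experiment(cfg, ref)

idx <- build_region_index(ref$ann)
category_distribution(do.call(c, sim$clip), idx)
#> Read class distribution over 150000 primary alignments:
#>        rRNA      snoRNA       snRNA   mRNA exon mRNA intron     lincRNA
#>      0.2045      0.0316      0.0387      0.5101      0.1758      0.0290
#> unannotated
#>      0.0103

scores   <- window_scores(sim$clip, sim$input, chrom_sizes = ref$ann$chrom_sizes)
clusters <- call_clusters(scores)        # "results"-variant filters
cluster_recovery(clusters, ref$truth$clusters)
#> $recall    [1] 1
#> $precision [1] 0.158
```

Recall is 1: every planted cluster is found. Precision against the planted
set is low *by design* here — the default study draws 50% of CLIP reads from
unspliced precursors versus 15% in the input, so introns are genuinely
enriched and correctly called; with matched precursor fractions (the
benchmark configuration) precision is ~1.

```r
sites <- lapply(sim$clip, call_crosslink_sites)   # 18 sites per replicate
rank_motifs(sites, ref$genome, k_range = 5, aln_sets = sim$clip, seed = 1)
#> Motif enrichment table: 236 k-mers; top 3 by combined p:
#>    kmer k fg_with bg_with p_combined p_bonferroni fg_fraction
#> 1 TCTCC 5      36       9  2.953e-23    3.024e-20      0.6667
#> 2 GCATG 5      12       0  5.108e-08    5.231e-05      0.2222
#> 3 CTCCA 5      15       5  1.684e-07    1.725e-04      0.2778
```

The planted 5-mer (written into the genome at 60% of crosslink sites) ranks
first; `fg_fraction` is the share of crosslink-site flanks containing it.

```r
cfg60 <- sim_config(seed = 1, n_genes = 60, genome_len = 400000)
de <- simulate_exon_de_table(cfg60, simulate_reference(cfg60)$ann)
last_exon_enrichment(de)
#> Last-exon DE enrichment (padj < 0.05 , |log2FC| >= 0)
#>          DE not_DE
#> last     48     12
#> internal  9    195
#> odds ratio = 86.67 ; Fisher exact p = 5.15e-32
```

With 80% of last exonic parts planted DE-up, the 2x2 last-vs-internal test
is extremely significant and `direction_summary(de)` shows the planted
48-up/0-down split exactly.

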