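# epromoterscan

Stress responses (heat shock, inflammation, genotoxic and respiratory stress,
hormone signalling, ...) induce sets of genes that are not scattered at random
across the genome: many sit within ~100 kb of another induced gene, forming
clusters of co-induced genes. Within such a cluster, one promoter often works
as an **Epromoter** — a promoter with dual promoter/enhancer activity that
recruits the key stress transcription factor (e.g. HSF1/HSF2 for heat shock)
on behalf of its neighbours, whose own promoters stay unbound.

`epromoterscan` is an R package for regulatory genomicists that identifies
these Epromoter-regulated clusters from processed data, and quantifies the
genomic proximity bias of induced genes. It consumes three files per dataset —
an induced-gene list with fold changes (TSV), TF ChIP-seq peaks (BED), and a
UCSC refGene annotation — plus optional TAD intervals (BED) and motif
occurrence tracks (BED).

## Method

1. **Clustering.** Induced genes are clustered either by TSS proximity
   (consecutive canonical TSSs strictly less than 100 kb apart are chained;
   clusters need more than one gene) or by co-membership in a topologically
   associating domain (TAD).
2. **Promoter binding.** A gene's promoter is TF-bound when any peak overlaps
   the ±1 kb window around any of its TSSs, *including alternative TSSs*.
3. **Epromoter call.** A cluster is Epromoter-regulated when the number of
   induced genes exceeds the number of TF-bound promoters (n_bound < n_genes,
   with n_bound ≥ 1); for TAD clusters the stricter default is exactly one
   bound promoter. Bound genes are the candidate Epromoters, the unbound
   genes their co-induced targets.
4. **Proximity statistics.** Nearest-TSS distance distributions of induced
   genes are compared against seeded random gene nulls of the same size
   (two-sample Kolmogorov–Smirnov test) and summarized by a signed Q–Q
   **deviation score**: both samples are reduced to K = 1000 quantiles and
   the score is Σₖ (q_induced(k) − q_random(k))/√2, the summed Euclidean
   distance of the Q–Q points to the identity line — negative when induced
   genes lie closer together than random genes. The distribution summit
   (mode on a log10 axis) and the fraction of genes within 100 kb complete
   the report.
5. **Annexes.** Motif occurrences (e.g. JASPAR HSF1/HSF2 scans) are counted
   in −1250/+750 bp promoter windows and binned (0 / 1 / 2–3 / >3) across
   five promoter categories; TF peaks around each cluster (span ±100 kb) are
   profiled as TSS-proximal (within 1 kb of any annotated TSS) or distal.

A synthetic-fixture generator (`make_genome()`, `plant_clusters()`,
`simulate_proximity()`) builds toy genomes with planted, fully known
Epromoter structure in the exact input formats the pipeline reads, so every
stage is testable without downloads.

## Worked example

```r
library(epromoterscan)

genome <- make_genome(n_chrom = 2, genes_per_chrom = 300, chrom_len = 1e7,
                      min_gene_spacing = 10000, seed = 7)
truth <- plant_clusters(genome, n_clusters = 6, genes_per_cluster = 3,
                        n_singletons = 4, seed = 8)
paths <- write_fixture(truth, "hs_fixture")

run <- run_epromoter_pipeline(
  annotation = paths$annotation, induced = paths$induced,
  peaks = list(HSF1 = paths$peaks), tads = paths$tads,
  dataset_id = "hs_demo", out_dir = "hs_fixture/out"
)
print(run)
#> epromoter_run 'hs_demo'
#>   dataset hs_demo (custom); 22 induced symbols, 22 matched, 0 missing
#>   method distance (fewer_than_n): 6 clusters (18 genes), 6 epromoter_regulated, 0 all_bound, 0 unbound, 0 partial_multi
#>   method tad (exactly_one): 6 clusters (18 genes), 6 epromoter_regulated, 0 all_bound, 0 unbound, 0 partial_multi
```

All 6 planted clusters are recovered by both clustering methods and
classified as Epromoter-regulated (one bound promoter, two co-induced genes
each); the 4 planted singletons stay unclustered. The proximity statistics on
the same induced set show the planted clustering signal:

```r
proximity_report(run$induced_genes, genome, seed = 11)
#> proximity_report 'induced'
#>   K-S D = 0.6364, p = 0.000168
#>   deviation score = -157507.08 kb (per-quantile mean -157.5071 kb)
#>   summit: induced 36.4 kb vs random 556.4 kb
#>   within 100 kb: induced 81.8% vs random 18.2%
```

The negative deviation score and the left-shifted summit say the induced
genes sit much closer to each other than a same-sized random gene set.
`out_dir` receives the two standard result files per method —
`clusters_with_tf_binding_*.tsv` (one row per cluster gene with per-TF bound
flags) and `epromoter_clusters_*.tsv` (one row per Epromoter-regulated
cluster with its epromoter and co-induced genes) — plus the summary JSON,
the bubble-grid occupancy table, the resolved config, and a run log.

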