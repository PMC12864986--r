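---
title: "Detecting Epromoter-regulated clusters of stress-induced genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Epromoter-regulated clusters of stress-induced genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epromoterscan)
```

## The model

Stress-induced genes are frequently organized in genomic clusters, and within
a cluster a single promoter — an *Epromoter*, a promoter with dual
promoter/enhancer function — often recruits the key stress transcription
factor for the whole neighbourhood. `epromoterscan` operationalizes this
observation as a small set of deterministic rules over three processed
inputs: an induced-gene list with fold changes, TF ChIP-seq peaks, and a UCSC
refGene annotation (optionally TAD intervals and motif tracks).

The calling model is intentionally simple and fully auditable:

* **Gene model.** Transcripts are collapsed per gene symbol. The TSS is
  strand-aware (`txStart` on `+`, `txEnd − 1` on `−`; refGene coordinates are
  0-based half-open, and so is everything internal to the package). A gene
  keeps the set of *all* alternative TSSs for binding decisions, and one
  *canonical* TSS — the 5′-most in the direction of transcription — for
  distances and clustering. The collapse rule is a package decision: the
  induced-gene lists are symbol-keyed and the clustering needs one
  representative coordinate per gene; taking the 5′-most TSS is the
  convention closest to "the" annotated start. It is exposed rather than
  hidden: alternative TSSs still drive the binding test below, which is
  where the choice could bias calls.
* **Clustering.** On each chromosome, induced genes sorted by canonical TSS
  chain whenever consecutive TSSs are strictly less than `max_gap` = 100 kb
  apart (single-linkage along the chromosome; on a line this equals the
  connected components of the pairwise <100 kb graph, which the tests assert
  against an O(n²) oracle). Clusters need ≥2 genes; leftovers are reported
  as singletons. The alternative TAD method assigns each gene to every TAD
  containing its canonical TSS (half-open containment) with no intra-TAD
  distance limit; nested TADs may produce overlapping clusters, and a
  `smallest_only` switch restricts genes to their smallest containing TAD
  for users who prefer a partition.
* **Binding and calling.** A promoter is bound when any peak shares ≥1 bp
  with the ±1 kb window around *any* of the gene's TSSs; binding is OR-ed
  over the dataset's key TFs (heat shock has two, HSF1 and HSF2). A cluster
  is `epromoter_regulated` when 1 ≤ n_bound < n_genes (`fewer_than_n`, the
  default for distance clusters), `all_bound` when every promoter is bound,
  and `unbound` otherwise. TAD clusters default to the stricter
  `exactly_one` criterion; clusters with 2 ≤ n_bound < n_genes are then kept
  visible as `partial_multi` rather than silently dropped or promoted,
  because such mixed configurations are biologically real but ambiguous.
  The category partition (epromoter + all_bound + unbound + partial_multi =
  all clusters) is asserted on every summary.

## Proximity statistics

To ask whether induced genes sit closer together than chance, each gene
contributes its nearest-neighbour distance: the minimum |TSS − TSS′| over
other genes of the set on the same chromosome, excluding co-located TSSs
(the ignore-overlap contract of a closest-feature scan; distances are plain
point differences, not edge gaps — immaterial at kb scale but fixed for
determinism). Genes alone on their chromosome are excluded and counted. The
null is a uniform, seeded, same-size sample of the protein-coding universe.

Three summaries are computed:

* **Two-sample K-S test** (`stats::ks.test`, two-sided) between the induced
  and random distance samples.
* **Deviation score**: both samples are reduced to K = 1000 quantiles at
  p&#8342; = (k − 0.5)/K with linear interpolation (`stats::quantile`
  type 7); each Q–Q point (random on x, induced on y) contributes its signed
  Euclidean distance to the identity line, (q_I − q_R)/√2, and the score is
  the sum. It is exactly 0 for identical samples, exactly antisymmetric
  under argument swap, and equals −K·c/√2 for a constant shift by c (the
  tests check this closed form at 10⁻⁹ relative tolerance). Negative scores
  mean induced genes are closer than random. The scale of a summed-quantile
  score depends on K and on the distance units, which published magnitudes
  do not pin down; the package therefore defaults to kb and exposes both the
  sum and the per-quantile mean, and treats the sign and the
  clumped-vs-uniform separation — not a specific magnitude — as the
  meaningful output.
* **Distribution summit**: distances are log10-transformed, a Gaussian KDE
  with a normal-reference (Scott-type, `bw.nrd`) bandwidth is evaluated on a
  512-point grid spanning the data, and the summit is the back-transformed
  argmax in kb. The log scale matches how such distributions are displayed
  and makes the estimator scale-equivariant (scaling distances by 10 moves
  the summit exactly one decade, a tested property). If the normal-reference
  bandwidth degenerates (near-constant samples) a standard-deviation
  fallback keeps the estimator defined; samples under 10 points are refused.
* **Fraction within 100 kb** uses an inclusive threshold (≤), documented
  because the boundary convention changes results on round distances.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_gap` | 100,000 | bp | cluster rule: consecutive TSS distance strictly below this chains genes; chosen where nearest-TSS distance summits of induced genes concentrate (~50–90 kb) |
| `flank` | 1,000 | bp | ±1 kb TSS-proximal window for TF binding; window is [TSS−1000, TSS+1001), both flanks plus the TSS base |
| `criterion` | `fewer_than_n` / `exactly_one` | — | Epromoter rule for distance / TAD clusters respectively |
| `upstream`/`downstream` (motifs) | 1,250 / 750 | bp | asymmetric promoter window for motif counting, applied strand-aware (configurable) |
| `n_quantiles` | 1,000 | — | Q–Q points of the deviation score |
| `threshold` | 100,000 | bp | within-distance fraction |
| `pad` | 100,000 | bp | cluster-span extension for proximal/distal peak profiling; proximal = within 1 kb of any annotated TSS |
| `seed` | required | — | every stochastic step (nulls, random promoter controls, simulation) takes an explicit seed; there is no hidden RNG state |

Defaults reproduce the standard analysis; every one is a function argument.

## What the synthetic generator emulates — and what it does not

`make_genome()` draws non-overlapping canonical TSSs by a
uniform-with-exclusion process (uniform draws on the spacing-shrunk
chromosome plus fixed offsets), random strands, and 0–2 alternative TSSs
within 5 kb downstream. `plant_clusters()` adds clusters whose consecutive
TSS gaps are drawn below 100 kb, gives each cluster a configured number of
bound promoters (a peak dropped inside the ±1 kb window), places induced
singletons far from all other induced genes, spans each cluster with a TAD
(150 kb margins), and can plant motif occurrences per promoter role and
distal peaks kept >1 kb away from every TSS window. Clusters and singletons
occupy disjoint slots wide enough that planted structures cannot merge, so
planted truth is exactly recoverable — tests assert precision = recall = 1
across seeds, and that TAD and distance clustering agree on these fixtures.
`simulate_proximity()` draws uniform (null) or clumped (clusters of
`clump_size` genes within `clump_spread`) induced sets for the power and
calibration checks of the deviation score.

These fixtures emulate the *geometry* of real datasets, not their content:
no sequence, no expression noise, no peak-calling artifacts, no
chromosome-scale gene-density gradients, no overlapping or bidirectional
gene structures beyond what the annotation collapse handles. Passing the
planted-truth tests therefore demonstrates that the rules are implemented
exactly, not that the rules recover biology from noisy real data.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; conversion to 1-based closed
  happens only at the GenomicRanges boundary (overlap counting is delegated
  to `GenomicRanges::countOverlaps`, BED I/O to `rtracklayer`).
* "±1 kb" is implemented as the 2001-bp half-open window
  [TSS−1000, TSS+1001) so that peak-overlap results are bit-stable and the
  boundary behaviour is testable.
* Strict `<` at `max_gap` (a 100,000 bp gap does not chain), inclusive `≤`
  at the within-threshold fraction; both boundaries are unit-tested.
* Cluster ids are deterministic (`<dataset>:<method>:<chrom>:<index>` with
  the index by leftmost TSS), and all outputs are byte-reproducible under a
  fixed config and seed (tested).
* The "common cluster" rule between methods — gene-set intersection with
  greedy one-to-one matching by descending intersection size, ties broken by
  id — is a package decision; exhaustive matching agrees on the tested toy
  cases.
* Non-redundant cross-dataset merging links Epromoter-regulated clusters
  sharing ≥1 gene symbol within a genome build (union-find connected
  components; builds never merge). Merging by coordinates instead of symbols
  is a plausible alternative; symbol-linking was chosen because the input
  lists are symbol-keyed and build-mixed coordinate lifts are out of scope.
  The merged total is sensitive to this rule.
* Multiple motif tracks (HSF1 + HSF2) are pooled by summing counts; analyzing
  them jointly but unpooled is possible by calling `count_motifs()` per
  track.
* Degenerate inputs have defined behaviour: empty peak files give all-unbound
  clusters and valid empty outputs; empty induced lists and zero annotation
  matches are explicit errors; induced symbols missing from the annotation
  are counted and logged, not fatal; chromosome-naming mismatches
  ("chr1" vs "1") are auto-reconciled to the annotation's style.

## Problem sizes

The test suite and the acceptance script run entirely on generated fixtures:
toy genomes of 2–4 chromosomes × 100–500 genes (10 Mb, 10 kb minimum
spacing), 5–50 planted clusters across ten seeds, 100-seed power and
200-seed calibration loops for the deviation score, and 10,000-draw
uniformity checks for the null sampler. These sizes make every oracle
comparison exact and keep the whole suite in the tens of seconds while
exercising each rule at its boundaries.

## Limitations

* TADs are consumed as fixed intervals; stress-specific topology changes and
  Hi-C processing are out of scope.
* The pipeline consumes processed inputs (differential expression, peak
  calls); no upstream read processing is performed.
* When several promoters of a cluster are bound, the package reports them
  all as candidate Epromoters rather than scoring which one drives the
  cluster.
* Motif analysis counts precomputed occurrence tracks; it does not scan
  PWMs or compute enrichment p-values.
* The deviation-score magnitude depends on K and units (see above); compare
  scores only across datasets computed with identical settings.
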