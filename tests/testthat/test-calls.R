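# Promoter binding, cluster classification, dataset summaries, non-redundant
# merging, and proximal/distal peak profiling

test_that("promoter_bound applies the +/- 1 kb window over all alternative TSSs", {
  g <- toy_genes("A", 10000)
  expect_true(promoter_bound(g, genomic_intervals("chr1", 9500, 9600)))
  # window is [9000, 11001): a peak starting at 11001 misses
  expect_false(promoter_bound(g, genomic_intervals("chr1", 11001, 12000)))
  expect_true(promoter_bound(g, genomic_intervals("chr1", 11000, 12000)))
  # binding via an alternative TSS counts
  g2 <- toy_genes("B", 10000, all_tss = list(c(10000, 50000)))
  expect_true(promoter_bound(g2, genomic_intervals("chr1", 49100, 49300)))
  expect_false(promoter_bound(g2, genomic_intervals("chr1", 30000, 30200)))
  # OR across a named list of per-TF peak sets
  peaks <- list(HSF1 = genomic_intervals("chr1", 1, 2),
                HSF2 = genomic_intervals("chr1", 9900, 9950))
  expect_true(promoter_bound(g, peaks))
})

test_that("classify_clusters applies the fewer-than-n Epromoter rule", {
  g <- toy_genes(c("a", "b", "c", "d"), c(0, 50000, 90000, 130000))
  cl <- cluster_by_distance(g)
  expect_equal(nrow(cl), 1L)
  # no peak: unbound
  calls <- classify_clusters(cl, g, genomic_intervals("chr9", 1, 2))
  expect_equal(calls$category, "unbound")
  # all bound
  all_pk <- genomic_intervals("chr1", g$canonical_tss, g$canonical_tss + 10)
  expect_equal(classify_clusters(cl, g, all_pk)$category, "all_bound")
  # one bound of four -> epromoter_regulated with the right gene lists
  one <- classify_clusters(cl, g, genomic_intervals("chr1", 50000, 50010))
  expect_equal(one$category, "epromoter_regulated")
  expect_equal(one$epromoter_genes[[1]], "b")
  expect_setequal(one$coinduced_genes[[1]], c("a", "c", "d"))
  # exactly_one criterion demotes 2-of-4 to partial_multi
  two <- genomic_intervals("chr1", c(0, 50000), c(10, 50010))
  expect_equal(classify_clusters(cl, g, two, criterion = "fewer_than_n")$category,
               "epromoter_regulated")
  expect_equal(classify_clusters(cl, g, two, criterion = "exactly_one")$category,
               "partial_multi")
})

test_that("adding a peak never demotes a cluster (binding monotonicity)", {
  set.seed(19)
  g <- toy_genes(sprintf("g%d", 1:6), cumsum(c(1e5, rep(5e4, 5))))
  cl <- cluster_by_distance(g)
  rank <- c(unbound = 0, epromoter_regulated = 1, partial_multi = 1, all_bound = 2)
  peaks <- genomic_intervals("chr1", g$canonical_tss, g$canonical_tss + 10)
  for (k in 0:5) {
    before <- classify_clusters(cl, g, peaks[seq_len(k) + 0, , drop = FALSE])$category
    after <- classify_clusters(cl, g, peaks[seq_len(k + 1), , drop = FALSE])$category
    expect_gte(rank[after], rank[before])
  }
})

test_that("summarize_dataset computes category counts and binding shares", {
  g <- toy_genes(sprintf("g%d", 1:8), c(0, 5e4, 2e6, 2.05e6, 4e6, 4.05e6, 6e6, 6.05e6))
  cl <- cluster_by_distance(g)
  expect_equal(nrow(cl), 4L)
  # categories: E (1 of 2 bound), E, A (both bound), U (none)
  pk <- genomic_intervals("chr1", c(0, 2e6, 4e6, 4.05e6), c(10, 2e6 + 10, 4e6 + 10, 4.05e6 + 10))
  calls <- classify_clusters(cl, g, pk)
  s <- summarize_dataset(calls, "toy")
  expect_equal(s$summary$n_clusters, 4L)
  expect_equal(s$summary$n_epromoter_clusters, 2L)
  expect_equal(s$summary$freq_epromoter, 0.5)
  # among the 3 clusters with binding: two have exactly one bound gene
  expect_equal(s$summary$one_bound_share, 2 / 3)
  expect_equal(s$summary$fewer_bound_share, 2 / 3)
  expect_equal(sum(s$bubble$n_clusters), 4L)
  expect_equal(s$bubble$n_clusters[s$bubble$n_genes == 2 & s$bubble$n_bound == 1], 2L)
  # empty call list: zero counts, NA fractions
  s0 <- summarize_dataset(calls[0, ], "empty")
  expect_equal(s0$summary$n_clusters, 0L)
  expect_true(is.na(s0$summary$freq_epromoter))
})

test_that("merge_nonredundant links clusters sharing symbols within a build", {
  mk <- function(id, build, genes) {
    data.frame(dataset_id = "ds", genome_build = build, cluster_id = id,
               genes = I(list(genes)), stringsAsFactors = FALSE)
  }
  # same cluster in 2 datasets -> one component
  m <- merge_nonredundant(rbind(mk("c1", "hg19", c("a", "b")),
                                mk("c2", "hg19", c("a", "b"))))
  expect_equal(m$total, 1L)
  # chain via one shared gene + disjoint third -> 2 components
  m2 <- merge_nonredundant(rbind(mk("c1", "hg19", c("a", "b")),
                                 mk("c2", "hg19", c("b", "c")),
                                 mk("c3", "hg19", c("x", "y"))))
  expect_equal(m2$total, 2L)
  sizes <- sort(m2$components$n_clusters)
  expect_equal(sizes, c(1L, 2L))
  # identical symbols on different builds never merge
  m3 <- merge_nonredundant(rbind(mk("c1", "hg19", c("a", "b")),
                                 mk("c2", "mm10", c("a", "b"))))
  expect_equal(m3$total, 2L)
  # dataset order invariance
  rows <- rbind(mk("c1", "hg19", c("a", "b")), mk("c2", "hg19", c("b", "c")),
                mk("c3", "hg19", c("x", "y")), mk("c4", "mm10", c("a", "q")))
  m4 <- merge_nonredundant(rows)
  m5 <- merge_nonredundant(rows[c(3, 1, 4, 2), ])
  expect_equal(m4$total, m5$total)
  expect_equal(lapply(m4$components$symbols, sort), lapply(m5$components$symbols, sort))
})

test_that("peak_location_profile partitions peaks into proximal and distal", {
  genes <- toy_genes(c("e", "c1", "c2"), c(1e6, 1.05e6, 1.1e6))
  cl <- cluster_by_distance(genes)
  # single promoter peak -> proximal_only
  pk1 <- genomic_intervals("chr1", 1e6 - 50, 1e6 + 50)
  calls <- classify_clusters(cl, genes, pk1)
  p1 <- peak_location_profile(calls, pk1, genes)
  expect_equal(p1$location_class, "proximal_only")
  # promoter peak + one 50 kb from every TSS -> proximal_and_distal
  pk2 <- rbind(pk1, genomic_intervals("chr1", 1.15e6 + 50000, 1.15e6 + 50200))
  p2 <- peak_location_profile(calls, pk2, genes)
  expect_equal(p2$n_proximal_peaks, 1L)
  expect_equal(p2$n_distal_peaks, 1L)
  expect_equal(p2$location_class, "proximal_and_distal")
  # toy locus: partition equals a brute-force window check
  set.seed(3)
  all_g <- toy_genes(sprintf("g%d", 1:3), c(1e6, 1.04e6, 1.2e6))
  pks <- genomic_intervals("chr1", ps <- c(999500, 1.041e6, 1.15e6, 1.3e6), ps + 200)
  cl3 <- cluster_by_distance(all_g[1:2, ])
  calls3 <- classify_clusters(cl3, all_g, pks)
  p3 <- peak_location_profile(calls3, pks, all_g)
  win <- promoter_windows(all_g, 1000, 1000, strand_aware = FALSE)
  prox <- brute_overlap_counts(pks, win) > 0
  in_span <- pks$start < (cl3$span_end + 1e5) & pks$end > pmax(0, cl3$span_start - 1e5)
  expect_equal(p3$n_proximal_peaks, sum(prox & in_span))
  expect_equal(p3$n_distal_peaks, sum(!prox & in_span))
  # peaks beyond the +/- 100 kb extension are ignored entirely
  far <- genomic_intervals("chr1", 5e6, 5.0002e6)
  p4 <- peak_location_profile(calls, far, genes)
  expect_equal(p4$location_class, "none")
})
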