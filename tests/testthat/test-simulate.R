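# Synthetic fixture generator: genome, planted clusters, proximity simulation,
# and on-disk round trips

test_that("make_genome respects spacing, determinism, and capacity", {
  g <- make_genome(1, 10, 5e5, 10000, seed = 1)
  expect_equal(nrow(g), 10L)
  expect_true(all(diff(sort(g$canonical_tss)) >= 10000))
  expect_identical(make_genome(1, 10, 5e5, 10000, seed = 1), g)
  expect_false(identical(make_genome(1, 10, 5e5, 10000, seed = 2), g))
  expect_error(make_genome(1, 100, 5e5, 10000, seed = 1), "capacity")
  # canonical TSS is 5'-most across the alternative TSSs
  g2 <- make_genome(2, 200, 5e6, 10000, seed = 4)
  for (i in seq_len(nrow(g2))) {
    expect_true(g2$canonical_tss[i] %in% g2$all_tss[[i]])
    if (g2$strand[i] == "+") expect_equal(g2$canonical_tss[i], min(g2$all_tss[[i]]))
    else expect_equal(g2$canonical_tss[i], max(g2$all_tss[[i]]))
  }
})

test_that("TSS spacing is consistent with the uniform-with-exclusion process", {
  # the process is exchangeable across seeds: spacing distributions from two
  # independent seeds should not be distinguishable (self-consistency)
  s1 <- diff(sort(make_genome(1, 500, 1e7, 10000, seed = 21)$canonical_tss))
  s2 <- diff(sort(make_genome(1, 500, 1e7, 10000, seed = 22)$canonical_tss))
  expect_gt(suppressWarnings(stats::ks.test(s1, s2))$p.value, 0.01)
  expect_true(all(s1 >= 10000))
})

test_that("plant_clusters places peaks in Epromoter windows and regenerates identically", {
  g <- make_genome(2, 100, 5e6, 10000, seed = 3)
  tr <- plant_clusters(g, n_clusters = 5, genes_per_cluster = 3, n_singletons = 4, seed = 7)
  expect_identical(plant_clusters(g, n_clusters = 5, genes_per_cluster = 3,
                                  n_singletons = 4, seed = 7), tr)
  # every planted cluster satisfies the distance rule used to plant it
  for (cl in tr$clusters) {
    tss <- sort(tr$genes$canonical_tss[match(cl$members, tr$genes$symbol)])
    expect_true(all(diff(tss) < 1e5))
  }
  # every peak lies inside the +/- 1 kb window of its Epromoter's TSS
  ep_genes <- tr$genes[match(unlist(lapply(tr$clusters, `[[`, "epromoters")),
                             tr$genes$symbol), ]
  win <- promoter_windows(ep_genes, 1000, 1000, strand_aware = FALSE)
  expect_true(all(count_overlaps(tr$peaks, win) > 0))
  # infeasible geometry errors
  small <- make_genome(1, 10, 1e6, 10000, seed = 1)
  expect_error(plant_clusters(small, n_clusters = 50, seed = 1), "infeasible geometry")
})

test_that("all-bound planting yields all_bound clusters; TADs agree with distance clusters", {
  g <- make_genome(2, 100, 5e6, 10000, seed = 3)
  tr_all <- plant_clusters(g, n_clusters = 4, genes_per_cluster = 3,
                           epromoters_per_cluster = "all", n_singletons = 2, seed = 5)
  induced <- tr_all$genes[tr_all$genes$symbol %in% tr_all$induced$symbol, ]
  calls <- classify_clusters(cluster_by_distance(induced), tr_all$genes, tr_all$peaks)
  expect_true(all(calls$category == "all_bound"))
  # TAD margins guarantee both clustering methods recover identical memberships
  tr <- plant_clusters(g, n_clusters = 5, genes_per_cluster = 3, n_singletons = 3, seed = 11)
  ind <- tr$genes[tr$genes$symbol %in% tr$induced$symbol, ]
  cd <- cluster_by_distance(ind)
  ct <- cluster_by_tad(ind, tr$tads)
  expect_equal(cluster_signature(cd$genes), cluster_signature(ct$genes))
})

test_that("distal peaks are planted clear of every promoter window", {
  g <- make_genome(2, 100, 5e6, 10000, seed = 13)
  tr <- plant_clusters(g, n_clusters = 3, genes_per_cluster = 3, n_singletons = 2,
                       n_distal_peaks = 2, seed = 13)
  distal <- tr$peaks[grepl("^distal", tr$peaks$name), ]
  expect_equal(nrow(distal), 6L)
  win <- promoter_windows(tr$genes, 1000, 1000, strand_aware = FALSE)
  expect_true(all(count_overlaps(distal, win) == 0))
})

test_that("simulate_proximity draws uniform or clumped induced sets", {
  g <- make_genome(2, 200, 5e6, 10000, seed = 2)
  # n = |universe| gives the universe itself; deviation vs itself is exactly 0
  all_g <- simulate_proximity(g, nrow(g), seed = 1)
  expect_setequal(all_g$symbol, g$symbol)
  s <- nn_distances(all_g)
  expect_identical(deviation_score(s, nn_distances(g)), 0)
  # clumped draws produce clumps of the requested geometry
  cl <- simulate_proximity(g, 60, clumping = list(clump_size = 3, clump_spread = 40000),
                           seed = 5)
  expect_equal(nrow(cl), 60L)
  d <- nn_distances(cl)$distances
  expect_gt(mean(d <= 40000), 0.8)
  expect_identical(cl, simulate_proximity(g, 60,
                                          clumping = list(clump_size = 3, clump_spread = 40000),
                                          seed = 5))
})

test_that("fixtures round-trip through disk into identical downstream calls", {
  g <- make_genome(2, 80, 5e6, 10000, seed = 31)
  tr <- plant_clusters(g, n_clusters = 4, genes_per_cluster = 3, n_singletons = 3,
                       seed = 17)
  dir <- withr::local_tempdir()
  paths <- write_fixture(tr, dir)
  # the annotation round-trips: collapse of the written refGene equals the truth genes
  genes2 <- collapse_genes(load_annotation(paths$annotation))
  expect_equal(genes2$symbol, tr$genes$symbol)
  expect_equal(genes2$canonical_tss, tr$genes$canonical_tss)
  expect_equal(genes2$all_tss, tr$genes$all_tss)
  # peaks and induced list round-trip
  unrowname <- function(d) { rownames(d) <- NULL; d }
  expect_equal(unrowname(read_bed(paths$peaks)[, c("chrom", "start", "end")]),
               unrowname(tr$peaks[, c("chrom", "start", "end")]))
  ind2 <- read_induced_genes(paths$induced)
  expect_equal(ind2$symbol, tr$induced$symbol)
  # downstream calls from files equal calls from the in-memory truth
  ind_mem <- tr$genes[tr$genes$symbol %in% tr$induced$symbol, ]
  calls_mem <- classify_clusters(cluster_by_distance(ind_mem), tr$genes, tr$peaks)
  ind_dsk <- genes2[genes2$symbol %in% ind2$symbol, ]
  calls_dsk <- classify_clusters(cluster_by_distance(ind_dsk), genes2, read_bed(paths$peaks))
  expect_equal(calls_mem$category, calls_dsk$category)
  expect_equal(calls_mem$genes, calls_dsk$genes)
  # regeneration plus rewrite is byte-identical
  dir2 <- withr::local_tempdir()
  tr2 <- plant_clusters(g, n_clusters = 4, genes_per_cluster = 3, n_singletons = 3,
                        seed = 17)
  paths2 <- write_fixture(tr2, dir2)
  for (f in c("annotation", "induced", "peaks", "tads")) {
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  }
})
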