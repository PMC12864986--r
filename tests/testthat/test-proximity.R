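# Nearest-TSS distance statistics: samples, nulls, K-S, deviation score,
# summit, within-threshold fractions

test_that("nn_distances delegates to nearest-TSS logic and tracks exclusions", {
  g <- toy_genes(c("a", "b", "c"), c(0, 60000, 200000))
  s <- nn_distances(g)
  expect_setequal(s$distances, c(60000, 60000, 140000))
  expect_equal(s$n_excluded_singletons, 0L)
  # chromosome singletons are excluded, not errors
  g2 <- toy_genes(c("a", "b"), c(100, 100), chrom = c("chr1", "chr2"))
  s2 <- nn_distances(g2)
  expect_length(s2$distances, 0L)
  expect_equal(s2$n_excluded_singletons, 2L)
  expect_error(nn_distances(g[1, , drop = FALSE]), "at least 2")
  # order invariance
  set.seed(2)
  g3 <- toy_genes(sprintf("g%d", 1:40), sample.int(2e6, 40),
                  chrom = sample(c("chr1", "chr2"), 40, TRUE))
  s3a <- nn_distances(g3)
  s3b <- nn_distances(g3[sample.int(40), ])
  expect_equal(sort(s3a$distances), sort(s3b$distances))
})

test_that("random_gene_null is a seeded uniform sample without replacement", {
  g <- toy_genes(sprintf("g%d", 1:50), seq(0, 49) * 1e4)
  expect_setequal(random_gene_null(g, 50, seed = 3)$symbol, g$symbol)
  expect_identical(random_gene_null(g, 10, seed = 1), random_gene_null(g, 10, seed = 1))
  expect_error(random_gene_null(g, 51, seed = 1), "universe")
})

test_that("null sampling is uniform over the universe (Monte-Carlo)", {
  universe <- toy_genes(sprintf("g%d", 1:1000), seq_len(1000) * 1e4)
  n_draws <- 10000
  counts <- integer(1000)
  for (s in seq_len(n_draws)) {
    idx <- match(random_gene_null(universe, 100, seed = s)$symbol, universe$symbol)
    counts[idx] <- counts[idx] + 1L
  }
  p <- 0.1
  se <- sqrt(p * (1 - p) / n_draws)
  freq <- counts / n_draws
  # each gene's inclusion frequency within 3 binomial standard errors of 0.1,
  # allowing the handful of 3-sigma excursions expected among 1000 genes
  expect_gt(mean(abs(freq - p) <= 3 * se), 0.99)
  expect_lt(abs(mean(freq) - p), 1e-12)
})

test_that("ks_compare reproduces the two-sample ECDF supremum", {
  a <- distance_sample(1:100)
  expect_equal(ks_compare(a, a)$statistic, 0)
  expect_gt(ks_compare(a, a)$p_value, 0.99)
  b <- distance_sample(runif(50, 0.1, 1))
  c <- distance_sample(runif(50, 2, 3))
  expect_equal(ks_compare(b, c)$statistic, 1)
  expect_error(ks_compare(numeric(0), b), "empty")
  set.seed(9)
  base <- rlnorm(200, meanlog = 11, sdlog = 1)
  shifted <- base
  shifted[1:100] <- shifted[1:100] * 3
  expect_equal(ks_compare(base, shifted)$statistic, brute_ks_stat(base, shifted))
})

test_that("deviation_score is zero on identity, antisymmetric, and matches the shift closed form", {
  set.seed(31)
  x <- runif(500, 5e4, 5e5)
  expect_identical(deviation_score(x, x), 0)
  y <- runif(300, 4e4, 4e5)
  expect_identical(deviation_score(x, y), -deviation_score(y, x))
  # constant shift: every quantile moves by -c, so the score is -K*c/sqrt(2)
  cshift <- 1234
  K <- 1000
  got_bp <- deviation_score(x - cshift, x, n_quantiles = K, units = "bp")
  expect_equal(got_bp, -K * cshift / sqrt(2), tolerance = 1e-9)
  expect_equal(deviation_score(x - cshift, x, units = "kb"),
               -K * cshift / sqrt(2) / 1000, tolerance = 1e-9)
  expect_equal(deviation_score(x - cshift, x, units = "bp", summary = "mean"),
               -cshift / sqrt(2), tolerance = 1e-9)
  expect_error(deviation_score(numeric(0), x), "empty")
})

test_that("qq_table exposes the per-quantile deviations that sum to the score", {
  set.seed(8)
  a <- rlnorm(400, 11, 0.8)
  b <- rlnorm(350, 11.3, 0.7)
  tab <- qq_table(a, b, n_quantiles = 200)
  expect_equal(nrow(tab), 200L)
  expect_equal(sum(tab$dev), deviation_score(a, b, 200, units = "bp"))
})

test_that("distribution_summit finds the mode on the log scale", {
  set.seed(17)
  # near-degenerate sample at 50 kb
  d <- 50000 + sample(c(-1, 0, 1), 1000, replace = TRUE)
  expect_equal(distribution_summit(d), 50, tolerance = 0.01)
  # log-normal with known mode 100 kb (sigma 0.1 in log10)
  ln <- 10^rnorm(5000, mean = 5, sd = 0.1)
  expect_equal(distribution_summit(ln), 100, tolerance = 0.1)
  # scaling distances by 10 shifts the summit by one log10 unit exactly
  expect_equal(distribution_summit(ln * 10), 10 * distribution_summit(ln),
               tolerance = 1e-8)
  expect_error(distribution_summit(1:9), ">= 10")
})

test_that("fraction_within is boundary-inclusive", {
  expect_equal(fraction_within(rep(1e4, 5), 1e5), 1)
  expect_equal(fraction_within(c(50000, 100000, 150000), 100000), 2 / 3)
  expect_equal(fraction_within(c(5, 10), 0), 0)
})

test_that("proximity_report assembles all statistics deterministically", {
  g <- make_genome(2, 200, 5e6, 10000, seed = 2)
  ind <- simulate_proximity(g, 60, clumping = list(clump_size = 3, clump_spread = 40000),
                            seed = 4)
  r1 <- proximity_report(ind, g, seed = 9)
  r2 <- proximity_report(ind, g, seed = 9)
  expect_identical(r1[names(r1) != "induced_sample"], r2[names(r2) != "induced_sample"])
  expect_true(r1$ks_statistic >= 0 && r1$ks_statistic <= 1)
  expect_true(r1$frac_within_threshold_induced >= 0 && r1$frac_within_threshold_induced <= 1)
  expect_lt(r1$deviation_score, 0)  # clumped induced genes are closer than random
})

test_that("induced-gene TSV reader enforces the two-column contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tfold_change", "HSPA1A\t12.5", "DNAJB1\t8.1"), path)
  ind <- read_induced_genes(path)
  expect_equal(ind$symbol, c("HSPA1A", "DNAJB1"))
  expect_equal(ind$fold_change, c(12.5, 8.1))
  writeLines("symbol", path)
  expect_error(read_induced_genes(path), "2 columns")
})
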