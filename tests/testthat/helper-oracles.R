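# Brute-force oracles and tiny fixture builders, independent of the
# implementations they check.

# nearest other point per id: O(n^2) all-pairs scan, same chromosome,
# excluding identical coordinates
brute_nearest <- function(points) {
  out <- numeric(0)
  for (i in seq_len(nrow(points))) {
    others <- points[points$chrom == points$chrom[i] &
                       points$pos != points$pos[i], , drop = FALSE]
    if (nrow(others) == 0L) next
    d <- min(abs(others$pos - points$pos[i]))
    out <- c(out, stats::setNames(d, points$id[i]))
  }
  out
}

# per-query overlap counts: O(n*m) scan, half-open semantics
brute_overlap_counts <- function(queries, subjects) {
  vapply(seq_len(nrow(queries)), function(i) {
    sum(subjects$chrom == queries$chrom[i] &
          subjects$start < queries$end[i] &
          subjects$end > queries$start[i])
  }, integer(1))
}

# connected components of the pairwise < gap adjacency graph (BFS, O(n^2))
brute_components <- function(chrom, tss, gap) {
  n <- length(tss)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    chrom[i] == chrom[j] & abs(tss[i] - tss[j]) < gap & i != j
  })
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# sup |ECDF_a - ECDF_b| evaluated over all observed values
brute_ks_stat <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(xs) - stats::ecdf(b)(xs)))
}

# minimal gene table: one row per symbol, all_tss defaults to the canonical
toy_genes <- function(symbol, tss, chrom = "chr1", strand = "+", all_tss = NULL) {
  n <- length(symbol)
  if (is.null(all_tss)) all_tss <- as.list(tss)
  data.frame(symbol = symbol, chrom = rep_len(chrom, n),
             strand = rep_len(strand, n), canonical_tss = tss,
             is_coding = TRUE, all_tss = I(all_tss), stringsAsFactors = FALSE)
}

# canonical cluster membership as a sorted signature for set comparison
cluster_signature <- function(gene_lists) {
  sort(vapply(gene_lists, function(gs) paste(sort(gs), collapse = ","), "",
              USE.NAMES = FALSE))
}
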