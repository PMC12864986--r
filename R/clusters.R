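# Clustering of induced genes: chaining by TSS proximity (< 100 kb between
# consecutive TSSs) or co-membership in a topologically associating domain
# (TAD), plus the comparison of the two methods' Epromoter calls.

empty_clusters <- function() {
  data.frame(cluster_id = character(0), method = character(0),
             chrom = character(0), span_start = numeric(0), span_end = numeric(0),
             n_genes = integer(0), tad_id = character(0),
             genes = I(list()), tss = I(list()), stringsAsFactors = FALSE)
}

#' Cluster induced genes by TSS proximity
#'
#' Per chromosome, genes sorted by canonical TSS are chained whenever the gap
#' to the previous gene is strictly less than `max_gap`; maximal chains of two
#' or more genes become clusters (single-linkage along the chromosome, the
#' nearest-neighbour logic of the distance rule). The result is independent of
#' input order. Genes left out of every cluster are attached as the
#' `"singletons"` attribute.
#'
#' @param induced Gene table of induced genes ([collapse_genes()] subset).
#' @param max_gap Maximum TSS-to-TSS gap in bp, exclusive (default 100,000:
#'   consecutive TSSs must be less than 100 kb apart).
#' @param dataset_id Used in the deterministic cluster ids
#'   `"<dataset>:distance:<chrom>:<index>"` (index by leftmost TSS within the
#'   chromosome).
#' @return A cluster `data.frame` (`cluster_id`, `method`, `chrom`,
#'   `span_start`, `span_end`, `n_genes`, list-columns `genes` and `tss`
#'   ordered by TSS), with singleton gene symbols in `attr(, "singletons")`.
#' @export
cluster_by_distance <- function(induced, max_gap = 100000, dataset_id = "dataset") {
  if (is.null(induced) || nrow(induced) == 0L) {
    out <- empty_clusters()
    attr(out, "singletons") <- character(0)
    return(out)
  }
  g <- induced[order(induced$chrom, induced$canonical_tss, induced$symbol), , drop = FALSE]
  rows <- list()
  singletons <- character(0)
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, , drop = FALSE]
    tss <- gc$canonical_tss
    new_chain <- c(TRUE, diff(tss) >= max_gap)
    chain <- cumsum(new_chain)
    idx <- 0L
    for (k in unique(chain)) {
      members <- which(chain == k)
      if (length(members) < 2L) {
        singletons <- c(singletons, gc$symbol[members])
        next
      }
      idx <- idx + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = sprintf("%s:distance:%s:%d", dataset_id, chr, idx),
        method = "distance", chrom = chr,
        span_start = tss[members[1L]], span_end = tss[members[length(members)]] + 1,
        n_genes = length(members), tad_id = NA_character_,
        genes = I(list(gc$symbol[members])), tss = I(list(tss[members])),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_clusters()
  rownames(out) <- NULL
  attr(out, "singletons") <- singletons
  out
}

#' Cluster induced genes by TAD co-membership
#'
#' Each gene is assigned to every TAD containing its canonical TSS (half-open
#' containment: `start <= tss < end`); TADs holding two or more induced genes
#' become clusters. There is no distance threshold within a TAD. Nested or
#' overlapping TADs are tolerated and may yield overlapping clusters;
#' `smallest_only = TRUE` restricts each gene to its smallest containing TAD.
#' Genes contained in no TAD are attached as the `"unclustered"` attribute.
#'
#' @param induced Gene table of induced genes.
#' @param tads Interval `data.frame` of TADs (BED-style, 0-based half-open);
#'   an optional `name` column supplies TAD ids.
#' @param smallest_only Assign each gene only to its smallest containing TAD.
#' @param dataset_id Used in cluster ids `"<dataset>:tad:<chrom>:<index>"`.
#' @return A cluster `data.frame` as in [cluster_by_distance()], with `tad_id`
#'   filled and unclustered gene symbols in `attr(, "unclustered")`.
#' @export
cluster_by_tad <- function(induced, tads, smallest_only = FALSE,
                           dataset_id = "dataset") {
  if (is.null(induced) || nrow(induced) == 0L || is.null(tads) || nrow(tads) == 0L) {
    out <- empty_clusters()
    attr(out, "unclustered") <- if (is.null(induced)) character(0) else induced$symbol
    return(out)
  }
  tad_ids <- if (!is.null(tads$name)) as.character(tads$name)
             else sprintf("tad_%d", seq_len(nrow(tads)))
  g <- induced[order(induced$chrom, induced$canonical_tss, induced$symbol), , drop = FALSE]
  # gene x TAD containment by TSS point
  assign <- vector("list", nrow(tads))
  clustered <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(g))) {
    hit <- which(tads$chrom == g$chrom[i] &
                   tads$start <= g$canonical_tss[i] & g$canonical_tss[i] < tads$end)
    if (length(hit) == 0L) next
    if (smallest_only && length(hit) > 1L) {
      hit <- hit[which.min(tads$end[hit] - tads$start[hit])]
    }
    for (h in hit) assign[[h]] <- c(assign[[h]], i)
  }
  rows <- list()
  per_chrom_idx <- list()
  keep <- which(lengths(assign) >= 2L)
  # deterministic index by leftmost member TSS within each chromosome
  if (length(keep)) {
    leftmost <- vapply(keep, function(h) min(g$canonical_tss[assign[[h]]]), numeric(1))
    keep <- keep[order(tads$chrom[keep], leftmost)]
  }
  for (h in keep) {
    members <- assign[[h]]
    chr <- tads$chrom[h]
    idx <- (per_chrom_idx[[chr]] %||% 0L) + 1L
    per_chrom_idx[[chr]] <- idx
    clustered[members] <- TRUE
    tss <- g$canonical_tss[members]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = sprintf("%s:tad:%s:%d", dataset_id, chr, idx),
      method = "tad", chrom = chr,
      span_start = min(tss), span_end = max(tss) + 1,
      n_genes = length(members), tad_id = tad_ids[h],
      genes = I(list(g$symbol[members])), tss = I(list(tss)),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_clusters()
  rownames(out) <- NULL
  in_tad <- unique(unlist(lapply(which(lengths(assign) >= 1L), function(h) assign[[h]])))
  attr(out, "unclustered") <- g$symbol[setdiff(seq_len(nrow(g)), in_tad)]
  out
}

#' Compare Epromoter calls from the distance and TAD clustering methods
#'
#' A distance cluster and a TAD cluster are "common" when their gene-symbol
#' sets intersect; matching is greedy one-to-one by descending intersection
#' size (ties broken by cluster id for determinism). Unmatched clusters land
#' in the method-only buckets.
#'
#' @param calls_distance,calls_tad Cluster or call `data.frame`s (need
#'   `cluster_id` and the `genes` list-column), typically the
#'   Epromoter-regulated subsets from the same dataset.
#' @return A list with `common` (a `data.frame` of matched id pairs and shared
#'   gene counts), `distance_only` and `tad_only` (character vectors of ids).
#' @export
compare_methods <- function(calls_distance, calls_tad) {
  nd <- nrow(calls_distance)
  nt <- nrow(calls_tad)
  pairs <- expand.grid(i = seq_len(nd), j = seq_len(nt))
  if (nrow(pairs)) {
    pairs$shared <- mapply(function(i, j) {
      length(intersect(calls_distance$genes[[i]], calls_tad$genes[[j]]))
    }, pairs$i, pairs$j)
    pairs <- pairs[pairs$shared > 0L, , drop = FALSE]
    pairs <- pairs[order(-pairs$shared,
                         calls_distance$cluster_id[pairs$i],
                         calls_tad$cluster_id[pairs$j]), , drop = FALSE]
  }
  used_d <- logical(nd)
  used_t <- logical(nt)
  common <- data.frame(distance_cluster_id = character(0),
                       tad_cluster_id = character(0), n_shared = integer(0),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE
    used_t[j] <- TRUE
    common <- rbind(common, data.frame(
      distance_cluster_id = calls_distance$cluster_id[i],
      tad_cluster_id = calls_tad$cluster_id[j],
      n_shared = pairs$shared[r], stringsAsFactors = FALSE
    ))
  }
  list(common = common,
       distance_only = calls_distance$cluster_id[!used_d],
       tad_only = calls_tad$cluster_id[!used_t])
}
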