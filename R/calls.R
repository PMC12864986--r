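# Epromoter calling: per-promoter TF binding, cluster classification,
# per-dataset frequency summaries, non-redundant cross-dataset merging, and
# proximal/distal peak profiling around clusters.

#' Is a gene's promoter bound by the TF?
#'
#' A gene counts as promoter-bound when any peak shares at least 1 bp with the
#' +/- `flank` window around any of its TSSs, including alternative TSSs.
#'
#' @param genes Gene table.
#' @param peaks Interval `data.frame` of TF ChIP-seq peaks, or a named list of
#'   such tables (one per TF), reduced by OR across TFs.
#' @param flank Promoter half-width in bp (default 1000: the +/- 1 kb
#'   TSS-proximal region).
#' @return Named logical vector, one element per gene (names = symbols).
#' @export
promoter_bound <- function(genes, peaks, flank = 1000) {
  if (is.data.frame(peaks)) peaks <- list(TF = peaks)
  win <- promoter_windows(genes, upstream = flank, downstream = flank,
                          per_tss = TRUE, strand_aware = FALSE)
  bound <- rep(FALSE, nrow(win))
  for (pk in peaks) {
    bound <- bound | (count_overlaps(win, pk) > 0L)
  }
  hit <- tapply(bound, win$gene_symbol, any)
  out <- as.logical(hit[genes$symbol])
  names(out) <- genes$symbol
  out
}

# per-gene x per-TF bound table, for the "clusters with TF binding" output
bound_table <- function(genes, peaks, flank = 1000) {
  if (is.data.frame(peaks)) peaks <- list(TF = peaks)
  if (is.null(names(peaks)) || any(!nzchar(names(peaks)))) {
    names(peaks) <- sprintf("TF%d", seq_along(peaks))
  }
  out <- data.frame(gene_symbol = genes$symbol, stringsAsFactors = FALSE)
  for (tf in names(peaks)) {
    out[[paste0("bound_", tf)]] <- unname(promoter_bound(genes, peaks[[tf]], flank))
  }
  out$bound_any <- Reduce(`|`, out[-1L], accumulate = FALSE)
  out
}

#' Classify clusters by promoter-level TF binding
#'
#' Per cluster gene, a bound flag is computed with [promoter_bound()] (OR over
#' the dataset's key TFs, e.g. HSF1 and HSF2 for heat shock). A cluster is
#' `unbound` when no promoter is bound, `all_bound` when every promoter is
#' bound, and `epromoter_regulated` when at least one but fewer than all
#' promoters are bound — the rule that the number of induced genes exceeds the
#' number of TF-bound promoters. With `criterion = "exactly_one"` (the default
#' for TAD clusters, where only one bound promoter qualifies), clusters with
#' two or more but not all promoters bound are demoted to the reported
#' `partial_multi` subcategory.
#'
#' @param clusters Cluster `data.frame` from [cluster_by_distance()] or
#'   [cluster_by_tad()].
#' @param genes Gene table covering the clustered genes (supplies alternative
#'   TSSs).
#' @param peaks Peak table or named per-TF list of peak tables.
#' @param criterion `"fewer_than_n"` (default) or `"exactly_one"`.
#' @param flank Promoter half-width in bp.
#' @return A call `data.frame`: the cluster columns plus `n_bound`,
#'   `category`, and list-columns `bound_flags`, `epromoter_genes` (bound
#'   genes of Epromoter-regulated clusters) and `coinduced_genes` (their
#'   unbound co-induced neighbours).
#' @export
classify_clusters <- function(clusters, genes, peaks,
                              criterion = c("fewer_than_n", "exactly_one"),
                              flank = 1000) {
  criterion <- match.arg(criterion)
  out <- clusters
  out$n_bound <- integer(nrow(out))
  out$category <- character(nrow(out))
  out$bound_flags <- I(vector("list", nrow(out)))
  out$epromoter_genes <- I(vector("list", nrow(out)))
  out$coinduced_genes <- I(vector("list", nrow(out)))
  if (nrow(out) == 0L) return(out)
  syms <- unique(unlist(out$genes))
  bound <- promoter_bound(genes[match(syms, genes$symbol), , drop = FALSE], peaks, flank)
  for (i in seq_len(nrow(out))) {
    gs <- out$genes[[i]]
    flags <- unname(bound[gs])
    nb <- sum(flags)
    n <- length(gs)
    category <- if (nb == 0L) "unbound"
      else if (nb == n) "all_bound"
      else if (criterion == "exactly_one" && nb > 1L) "partial_multi"
      else "epromoter_regulated"
    out$n_bound[i] <- nb
    out$category[i] <- category
    out$bound_flags[[i]] <- flags
    if (category == "epromoter_regulated") {
      out$epromoter_genes[[i]] <- gs[flags]
      out$coinduced_genes[[i]] <- gs[!flags]
    } else {
      out$epromoter_genes[[i]] <- character(0)
      out$coinduced_genes[[i]] <- character(0)
    }
  }
  out
}

#' Summarize Epromoter calls for one dataset
#'
#' Counts clusters per category, the Epromoter-regulated frequency among all
#' clusters, and — among clusters harboring at least one TF-bound gene — the
#' share with exactly one bound promoter and the share with fewer bound
#' promoters than genes. Also emits the bubble-plot occupancy grid
#' (number of genes per cluster x number of bound genes).
#'
#' @param calls Call `data.frame` from [classify_clusters()].
#' @param dataset_id Dataset identifier.
#' @param n_induced_genes Optional count of induced genes in the dataset.
#' @return A list with `summary` (a one-row `data.frame`) and `bubble` (the
#'   occupancy grid: `n_genes`, `n_bound`, `n_clusters`).
#' @export
summarize_dataset <- function(calls, dataset_id = "dataset", n_induced_genes = NA_integer_) {
  n <- nrow(calls)
  cat_n <- function(k) sum(calls$category == k)
  n_ep <- cat_n("epromoter_regulated")
  n_ab <- cat_n("all_bound")
  n_ub <- cat_n("unbound")
  n_pm <- cat_n("partial_multi")
  stopifnot(n_ep + n_ab + n_ub + n_pm == n)  # category partition invariant
  with_binding <- calls$n_bound >= 1L
  nb <- sum(with_binding)
  summary <- data.frame(
    dataset_id = dataset_id,
    n_induced_genes = n_induced_genes,
    n_clusters = n,
    n_genes_in_clusters = if (n) sum(calls$n_genes) else 0L,
    n_epromoter_clusters = n_ep,
    n_all_bound_clusters = n_ab,
    n_unbound_clusters = n_ub,
    n_partial_multi_clusters = n_pm,
    freq_epromoter = if (n) n_ep / n else NA_real_,
    freq_all_bound = if (n) n_ab / n else NA_real_,
    one_bound_share = if (nb) sum(calls$n_bound[with_binding] == 1L) / nb else NA_real_,
    fewer_bound_share = if (nb) {
      sum(calls$n_bound[with_binding] < calls$n_genes[with_binding]) / nb
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  bubble <- if (n) {
    agg <- stats::aggregate(list(n_clusters = rep(1L, n)),
                            by = list(n_genes = calls$n_genes, n_bound = calls$n_bound),
                            FUN = sum)
    agg[order(agg$n_genes, agg$n_bound), , drop = FALSE]
  } else {
    data.frame(n_genes = integer(0), n_bound = integer(0), n_clusters = integer(0))
  }
  rownames(bubble) <- NULL
  list(summary = summary, bubble = bubble)
}

# minimal union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Merge Epromoter-regulated clusters across datasets into non-redundant sets
#'
#' Within each genome build, Epromoter-regulated clusters from all datasets
#' are nodes; two clusters are linked when they share at least one gene
#' symbol; connected components are the non-redundant clusters. Different
#' builds never merge. The result is invariant to dataset ordering.
#'
#' @param calls A `data.frame` with columns `dataset_id`, `genome_build`,
#'   `cluster_id` and the `genes` list-column (concatenated
#'   Epromoter-regulated calls; see [classify_clusters()]).
#' @return A list with `total` (the non-redundant cluster count over all
#'   builds) and `components` (one row per merged cluster: `component_id`,
#'   `genome_build`, `n_clusters`, semicolon-able list-columns `cluster_ids`
#'   and `symbols`).
#' @export
merge_nonredundant <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(total = 0L,
                components = data.frame(component_id = character(0),
                                        genome_build = character(0),
                                        n_clusters = integer(0),
                                        cluster_ids = I(list()), symbols = I(list()))))
  }
  comps <- list()
  for (build in sort(unique(as.character(calls$genome_build)))) {
    sub <- calls[calls$genome_build == build, , drop = FALSE]
    sub <- sub[order(sub$cluster_id), , drop = FALSE]  # order invariance
    n <- nrow(sub)
    parent <- uf_new(n)
    seen <- list()  # symbol -> first cluster index
    for (i in seq_len(n)) {
      for (s in sub$genes[[i]]) {
        if (is.null(seen[[s]])) seen[[s]] <- i
        else parent <- uf_union(parent, seen[[s]], i)
      }
    }
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    for (r in sort(unique(roots))) {
      members <- which(roots == r)
      comps[[length(comps) + 1L]] <- data.frame(
        component_id = sprintf("%s:nr%d", build, length(comps) + 1L),
        genome_build = build,
        n_clusters = length(members),
        cluster_ids = I(list(sub$cluster_id[members])),
        symbols = I(list(sort(unique(unlist(sub$genes[members]))))),
        stringsAsFactors = FALSE
      )
    }
  }
  components <- do.call(rbind, comps)
  rownames(components) <- NULL
  list(total = nrow(components), components = components)
}

#' Profile proximal vs distal TF peaks around clusters
#'
#' Each cluster span is extended by `pad` on both sides; peaks overlapping the
#' extended span are classified as proximal — within `flank` of any annotated
#' TSS (any gene of the annotation, induced or not, alternative TSSs
#' included) — or distal (intergenic).
#'
#' @param calls Call or cluster `data.frame` (needs `cluster_id`, `chrom`,
#'   `span_start`, `span_end`).
#' @param peaks Peak interval `data.frame`.
#' @param all_genes Full gene table of the annotation.
#' @param pad Span extension in bp (default 100,000).
#' @param flank TSS-proximal half-width in bp (default 1000).
#' @return A `data.frame` with `cluster_id`, `n_proximal_peaks`,
#'   `n_distal_peaks`, `location_class` in `{proximal_only,
#'   proximal_and_distal, distal_only, none}`.
#' @export
peak_location_profile <- function(calls, peaks, all_genes, pad = 100000, flank = 1000) {
  tss_win <- promoter_windows(all_genes, upstream = flank, downstream = flank,
                              per_tss = TRUE, strand_aware = FALSE)
  peak_proximal <- count_overlaps(peaks, tss_win) > 0L
  out <- data.frame(cluster_id = calls$cluster_id,
                    n_proximal_peaks = integer(nrow(calls)),
                    n_distal_peaks = integer(nrow(calls)),
                    location_class = character(nrow(calls)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    ext_start <- max(0, calls$span_start[i] - pad)
    ext_end <- calls$span_end[i] + pad
    sel <- peaks$chrom == calls$chrom[i] & peaks$start < ext_end & peaks$end > ext_start
    np <- sum(peak_proximal[sel])
    nd <- sum(sel) - np
    out$n_proximal_peaks[i] <- np
    out$n_distal_peaks[i] <- nd
    out$location_class[i] <- if (np > 0L && nd > 0L) "proximal_and_distal"
      else if (np > 0L) "proximal_only"
      else if (nd > 0L) "distal_only"
      else "none"
  }
  out
}
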