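# Motif density over promoter categories: assign induced genes to the five
# promoter categories, count motif occurrences in -1250/+750 bp promoter
# windows, and tabulate binned counts per category.

MOTIF_BINS <- c("0", "1", "2-3", ">3")

#' Assign promoters to the five motif-analysis categories
#'
#' Every induced gene maps to exactly one of: `epromoter` (the TF-bound genes
#' of Epromoter-regulated clusters), `coinduced` (their unbound cluster
#' neighbours), `induced_tf_plus` / `induced_tf_minus` (all other induced
#' genes, split by promoter TF binding); `n_random` non-induced genes sampled
#' from the universe form the `random` control. A gene appearing as both
#' epromoter and co-induced across overlapping (TAD) clusters is kept as
#' epromoter.
#'
#' @param calls Call `data.frame` from [classify_clusters()].
#' @param induced Gene table of induced genes.
#' @param bound Named logical vector of promoter TF-binding over the induced
#'   genes (e.g. from [promoter_bound()]).
#' @param universe Full gene table to draw random control promoters from
#'   (induced genes are excluded).
#' @param n_random Number of random control promoters.
#' @param seed Integer seed for the random control.
#' @return A `data.frame` with `gene_symbol` and `category`; categories are
#'   mutually exclusive.
#' @export
assign_categories <- function(calls, induced, bound, universe, n_random, seed) {
  ep_calls <- calls[calls$category == "epromoter_regulated", , drop = FALSE]
  epromoter <- unique(unlist(ep_calls$epromoter_genes))
  coinduced <- setdiff(unique(unlist(ep_calls$coinduced_genes)), epromoter)
  rest <- setdiff(induced$symbol, c(epromoter, coinduced))
  tf_plus <- rest[bound[rest]]
  tf_minus <- rest[!bound[rest]]
  pool <- setdiff(universe$symbol, induced$symbol)
  if (n_random > length(pool)) stop("n_random exceeds the non-induced universe")
  random <- with_seed(seed, sample(pool, n_random))
  cat_df <- function(sym, cat) {
    data.frame(gene_symbol = sym, category = rep_len(cat, length(sym)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    cat_df(epromoter, "epromoter"),
    cat_df(coinduced, "coinduced"),
    cat_df(tf_plus, "induced_tf_plus"),
    cat_df(tf_minus, "induced_tf_minus"),
    cat_df(random, "random")
  )
  stopifnot(!anyDuplicated(out$gene_symbol))  # categories are disjoint
  rownames(out) <- NULL
  out
}

#' Count motif occurrences per promoter window
#'
#' Overlap counts (>= 1 bp, half-open) of a genome-wide motif-occurrence
#' track, e.g. a JASPAR TFBS scan, against promoter windows — typically the
#' -1250/+750 bp windows from [promoter_windows()]. When several tracks are
#' given (e.g. HSF1 and HSF2 motifs) their counts are summed (pooled track).
#'
#' @param promoters Promoter-window `data.frame` ([promoter_windows()]).
#' @param motif_tracks Interval `data.frame`, or a list of them.
#' @return Integer vector of per-promoter motif counts.
#' @export
count_motifs <- function(promoters, motif_tracks) {
  if (is.data.frame(motif_tracks)) motif_tracks <- list(motif_tracks)
  counts <- integer(nrow(promoters))
  for (trk in motif_tracks) counts <- counts + count_overlaps(promoters, trk)
  counts
}

#' Bin motif counts into the standard categories
#'
#' @param counts Integer vector of motif counts.
#' @return Factor with levels `0`, `1`, `2-3`, `>3`.
#' @export
bin_motif_counts <- function(counts) {
  lab <- ifelse(counts >= 4, ">3", ifelse(counts >= 2, "2-3", as.character(counts)))
  factor(lab, levels = MOTIF_BINS)
}

#' Per-category motif-count bin table
#'
#' @param assignments Category `data.frame` from [assign_categories()] plus a
#'   `motif_count` column.
#' @return A list with `table` (per-gene rows with `bin`) and `percent` (per
#'   category and bin: `n` and `pct`; empty categories get `NA` percentages).
#'   Percentages sum to 100 within each non-empty category.
#' @export
motif_bin_table <- function(assignments) {
  stopifnot(all(c("gene_symbol", "category", "motif_count") %in% names(assignments)))
  tab <- assignments
  tab$bin <- bin_motif_counts(tab$motif_count)
  cats <- c("epromoter", "coinduced", "induced_tf_plus", "induced_tf_minus", "random")
  cats <- c(intersect(cats, unique(tab$category)),
            setdiff(unique(tab$category), cats))
  rows <- list()
  for (cat in cats) {
    sub <- tab[tab$category == cat, , drop = FALSE]
    n_bin <- table(sub$bin)
    tot <- nrow(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat, bin = MOTIF_BINS, n = as.integer(n_bin[MOTIF_BINS]),
      pct = if (tot) 100 * as.integer(n_bin[MOTIF_BINS]) / tot else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  percent <- do.call(rbind, rows)
  rownames(percent) <- NULL
  list(table = tab, percent = percent)
}

#' End-to-end motif-density analysis
#'
#' Assigns categories, builds strand-aware -1250/+750 bp promoter windows at
#' the canonical TSS, counts motif-track overlaps, and tabulates bins.
#'
#' @inheritParams assign_categories
#' @param genes Full gene table (supplies coordinates for every categorized
#'   gene, including the random controls).
#' @param motif_tracks Motif-occurrence track(s), see [count_motifs()].
#' @param upstream,downstream Window flanks in bp (defaults -1250/+750).
#' @return The [motif_bin_table()] result, with the assignments (including
#'   `motif_count`) under `$table`.
#' @export
motif_density_analysis <- function(calls, induced, bound, universe, genes,
                                   motif_tracks, n_random = 100, seed = 1,
                                   upstream = 1250, downstream = 750) {
  assignments <- assign_categories(calls, induced, bound, universe, n_random, seed)
  g <- genes[match(assignments$gene_symbol, genes$symbol), , drop = FALSE]
  if (anyNA(g$symbol)) stop("categorized gene absent from the gene table")
  win <- promoter_windows(g, upstream = upstream, downstream = downstream,
                          per_tss = FALSE, strand_aware = TRUE)
  assignments$motif_count <- count_motifs(win, motif_tracks)
  motif_bin_table(assignments)
}
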