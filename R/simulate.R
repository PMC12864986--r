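# Synthetic fixtures with planted ground truth: a toy gene annotation, induced
# sets with controlled proximity structure, planted Epromoter clusters with
# peaks, TADs and motif tracks, and writers that emit the exact input formats
# the pipeline reads. All randomness flows from explicit seeds.

#' Generate a toy gene annotation
#'
#' Places `genes_per_chrom` non-overlapping canonical TSSs per chromosome by a
#' uniform-with-exclusion process (uniform draws on the shrunk chromosome plus
#' a fixed spacing offset, guaranteeing pairwise distance >=
#' `min_gene_spacing`), assigns random strands, and gives each gene 0-2
#' alternative TSSs within 5 kb downstream of the canonical one (so the
#' canonical TSS stays 5'-most).
#'
#' @param n_chrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param genes_per_chrom Genes per chromosome.
#' @param chrom_len Chromosome length in bp.
#' @param min_gene_spacing Minimum canonical-TSS spacing in bp.
#' @param seed Integer seed.
#' @return A gene table ([collapse_genes()] layout) with chromosome lengths in
#'   `attr(, "chrom_lens")`.
#' @export
make_genome <- function(n_chrom = 4, genes_per_chrom = 500, chrom_len = 1e7,
                        min_gene_spacing = 10000, seed = 1) {
  if (genes_per_chrom * min_gene_spacing >= chrom_len) {
    stop("capacity violation: genes_per_chrom * min_gene_spacing must be < chrom_len")
  }
  genes <- with_seed(seed, {
    rows <- list()
    for (c in seq_len(n_chrom)) {
      chr <- sprintf("chr%d", c)
      g <- genes_per_chrom
      u <- sort(stats::runif(g, 0, chrom_len - g * min_gene_spacing))
      pos <- floor(u) + (seq_len(g) - 1) * min_gene_spacing
      strand <- sample(c("+", "-"), g, replace = TRUE)
      for (j in seq_len(g)) {
        n_alt <- sample(0:2, 1L)
        off <- if (n_alt) sample(500:5000, n_alt) else integer(0)
        alt <- if (strand[j] == "+") pos[j] + off else pmax(0, pos[j] - off)
        all_tss <- sort(unique(c(pos[j], alt)))
        rows[[length(rows) + 1L]] <- data.frame(
          symbol = sprintf("G%02d%04d", c, j), chrom = chr, strand = strand[j],
          canonical_tss = pos[j], is_coding = TRUE,
          all_tss = I(list(all_tss)), stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  genes <- genes[order(genes$chrom, genes$canonical_tss, genes$symbol), , drop = FALSE]
  rownames(genes) <- NULL
  attr(genes, "chrom_lens") <- stats::setNames(rep(chrom_len, n_chrom),
                                               sprintf("chr%d", seq_len(n_chrom)))
  attr(genes, "params") <- list(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
                                chrom_len = chrom_len,
                                min_gene_spacing = min_gene_spacing, seed = seed)
  genes
}

#' Plant Epromoter-regulated clusters into a toy genome
#'
#' Adds clusters of co-induced genes with known ground truth: each cluster's
#' genes sit on one chromosome with consecutive TSS gaps drawn from
#' `intra_gap_range` (all below the 100 kb rule), a configured number of genes
#' per cluster carries an Epromoter (a ChIP-seq peak dropped inside its
#' +/- 1 kb promoter window), induced singletons are placed far (> 100 kb)
#' from every other induced gene, and optional TADs span each cluster with a
#' margin. Clusters and singletons occupy disjoint genomic slots wide enough
#' that planted structures can never merge, so the planted truth is exactly
#' what the pipeline should recover.
#'
#' @param genome Gene table from [make_genome()].
#' @param n_clusters Number of planted clusters.
#' @param genes_per_cluster Genes per planted cluster (>= 2).
#' @param intra_gap_range Length-2 range (bp) for consecutive TSS gaps; the
#'   maximum must be below 100,000.
#' @param n_singletons Induced genes planted far from any other induced gene.
#' @param epromoters_per_cluster Bound promoters per cluster: an integer
#'   (default 1) or `"all"` (every promoter bound).
#' @param peak_width Width of planted peaks in bp.
#' @param n_distal_peaks Distal (intergenic) peaks added per cluster, placed
#'   inside the cluster span but > 1 kb away from every TSS in the genome.
#' @param with_tads Emit one TAD per cluster.
#' @param tad_margin TAD margin beyond the cluster span in bp.
#' @param motif_hits Optional named vector
#'   `c(epromoter = ..., coinduced = ...)`: motif occurrences planted inside
#'   the -1250/+750 window of each cluster gene by role.
#' @param seed Integer seed.
#' @return An object of class `epromoter_truth`: list with `genes` (genome
#'   plus planted genes), `induced` (`symbol`, `fold_change`), `clusters`
#'   (each with `members`, `epromoters`, `coinduced`, `chrom`), `singletons`,
#'   `tads`, `peaks`, `motif_track`, `seed`, `params`.
#' @export
plant_clusters <- function(genome, n_clusters = 10, genes_per_cluster = 3,
                           intra_gap_range = c(20000, 80000), n_singletons = 10,
                           epromoters_per_cluster = 1, peak_width = 200,
                           n_distal_peaks = 0, with_tads = TRUE,
                           tad_margin = 150000, motif_hits = NULL, seed = 1) {
  stopifnot(genes_per_cluster >= 2, max(intra_gap_range) < 100000,
            min(intra_gap_range) >= 1)
  chrom_lens <- attr(genome, "chrom_lens")
  if (is.null(chrom_lens)) {
    chrom_lens <- tapply(genome$canonical_tss, genome$chrom, max) + 2e5
  }
  max_width <- (genes_per_cluster - 1) * max(intra_gap_range)
  slot_w <- max_width + 2 * (tad_margin + 10000)
  slots <- do.call(rbind, lapply(names(chrom_lens), function(chr) {
    k <- floor(chrom_lens[[chr]] / slot_w)
    if (k < 1L) return(NULL)
    data.frame(chrom = chr, slot_start = (seq_len(k) - 1) * slot_w,
               stringsAsFactors = FALSE)
  }))
  n_items <- n_clusters + n_singletons
  n_avail <- if (is.null(slots)) 0L else nrow(slots)
  if (n_avail < n_items) {
    stop(sprintf("infeasible geometry: no slot for planted cluster %d (only %d slots available)",
                 n_avail + 1L, n_avail))
  }
  truth <- with_seed(seed, {
    pick <- slots[sample.int(nrow(slots), n_items), , drop = FALSE]
    new_rows <- list()
    clusters <- list()
    peaks <- list()
    tads <- list()
    motifs <- list()
    for (k in seq_len(n_clusters)) {
      chr <- pick$chrom[k]
      anchor <- pick$slot_start[k] + tad_margin + 10000
      gaps <- floor(stats::runif(genes_per_cluster - 1,
                                 intra_gap_range[1], intra_gap_range[2] + 1))
      tss <- anchor + c(0, cumsum(gaps))
      syms <- sprintf("PC%03d_%d", k, seq_len(genes_per_cluster))
      n_ep <- if (identical(epromoters_per_cluster, "all")) genes_per_cluster
        else min(as.integer(epromoters_per_cluster), genes_per_cluster)
      ep_idx <- sort(sample.int(genes_per_cluster, n_ep))
      for (j in seq_len(genes_per_cluster)) {
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          symbol = syms[j], chrom = chr, strand = "+",
          canonical_tss = tss[j], is_coding = TRUE,
          all_tss = I(list(tss[j])), stringsAsFactors = FALSE
        )
      }
      for (j in ep_idx) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chr, start = tss[j] - floor(peak_width / 2),
          end = tss[j] + ceiling(peak_width / 2),
          name = sprintf("peak_%s", syms[j]), stringsAsFactors = FALSE
        )
      }
      if (with_tads) {
        tads[[length(tads) + 1L]] <- data.frame(
          chrom = chr, start = max(0, tss[1] - tad_margin),
          end = tss[genes_per_cluster] + tad_margin,
          name = sprintf("tad_%03d", k), stringsAsFactors = FALSE
        )
      }
      if (!is.null(motif_hits)) {
        for (j in seq_len(genes_per_cluster)) {
          role <- if (j %in% ep_idx) "epromoter" else "coinduced"
          n_hit <- motif_hits[[role]] %||% 0
          if (n_hit > 0) for (h in seq_len(n_hit)) {
            # inside the -1250/+750 window of a '+' gene
            s <- tss[j] - 1000 + (h - 1) * 120
            motifs[[length(motifs) + 1L]] <- data.frame(
              chrom = chr, start = s, end = s + 10,
              name = sprintf("motif_%s_%d", syms[j], h), stringsAsFactors = FALSE
            )
          }
        }
      }
      clusters[[k]] <- list(members = syms, epromoters = syms[ep_idx],
                            coinduced = syms[setdiff(seq_len(genes_per_cluster), ep_idx)],
                            chrom = chr)
    }
    singleton_syms <- character(0)
    for (k in seq_len(n_singletons)) {
      chr <- pick$chrom[n_clusters + k]
      tss <- pick$slot_start[n_clusters + k] + floor(slot_w / 2)
      sym <- sprintf("PS%03d", k)
      singleton_syms <- c(singleton_syms, sym)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        symbol = sym, chrom = chr, strand = "+", canonical_tss = tss,
        is_coding = TRUE, all_tss = I(list(tss)), stringsAsFactors = FALSE
      )
    }
    planted <- do.call(rbind, new_rows)
    induced_syms <- planted$symbol
    genes <- rbind(genome, planted)
    genes <- genes[order(genes$chrom, genes$canonical_tss, genes$symbol), , drop = FALSE]
    rownames(genes) <- NULL
    attr(genes, "chrom_lens") <- chrom_lens
    peaks_df <- if (length(peaks)) do.call(rbind, peaks) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 name = character(0), stringsAsFactors = FALSE)
    if (n_distal_peaks > 0) {
      all_tss_by_chrom <- split(unlist(genes$all_tss),
                                rep(genes$chrom, lengths(genes$all_tss)))
      for (k in seq_len(n_clusters)) {
        chr <- clusters[[k]]$chrom
        first_tss <- min(vapply(clusters[[k]]$members, function(s) {
          genes$canonical_tss[genes$symbol == s]
        }, numeric(1)))
        cand <- first_tss + 5000
        tvec <- all_tss_by_chrom[[chr]]
        for (d in seq_len(n_distal_peaks)) {
          # advance until > 1 kb + peak width clear of every TSS window
          while (any(abs(tvec - cand) <= 1000 + peak_width) ||
                 any(abs(tvec - (cand + peak_width)) <= 1000 + peak_width)) {
            cand <- cand + 2500
          }
          peaks_df <- rbind(peaks_df, data.frame(
            chrom = chr, start = cand, end = cand + peak_width,
            name = sprintf("distal_%03d_%d", k, d), stringsAsFactors = FALSE
          ))
          cand <- cand + peak_width + 2500
        }
      }
    }
    list(
      genes = genes,
      induced = data.frame(symbol = induced_syms,
                           fold_change = round(stats::runif(length(induced_syms), 2, 10), 2),
                           stringsAsFactors = FALSE),
      clusters = clusters,
      singletons = singleton_syms,
      tads = if (length(tads)) do.call(rbind, tads) else NULL,
      peaks = peaks_df,
      motif_track = if (length(motifs)) do.call(rbind, motifs) else NULL
    )
  })
  truth$seed <- as.integer(seed)
  truth$params <- list(n_clusters = n_clusters, genes_per_cluster = genes_per_cluster,
                       intra_gap_range = intra_gap_range, n_singletons = n_singletons,
                       epromoters_per_cluster = epromoters_per_cluster,
                       peak_width = peak_width, n_distal_peaks = n_distal_peaks,
                       with_tads = with_tads, tad_margin = tad_margin,
                       motif_hits = motif_hits)
  class(truth) <- "epromoter_truth"
  truth
}

#' Simulate an induced gene set with controlled proximity structure
#'
#' `clumping = "none"` draws a uniform subsample of the universe — the null
#' for the proximity statistics. A clumped draw picks random anchor genes and
#' takes the `clump_size` genes nearest to each anchor within `clump_spread`
#' bp, emulating co-induced gene neighbourhoods; if the universe cannot host
#' enough clumps the remainder is filled uniformly.
#'
#' @param universe Gene table.
#' @param n_induced Number of induced genes to draw.
#' @param clumping `"none"` or a list `list(clump_size =, clump_spread =)`.
#' @param seed Integer seed.
#' @return A gene table of `n_induced` rows.
#' @export
simulate_proximity <- function(universe, n_induced, clumping = "none", seed = 1) {
  stopifnot(n_induced <= nrow(universe))
  if (identical(clumping, "none")) {
    return(random_gene_null(universe, n_induced, seed))
  }
  stopifnot(is.list(clumping), !is.null(clumping$clump_size), !is.null(clumping$clump_spread))
  idx <- with_seed(seed, {
    anchors <- sample.int(nrow(universe))
    taken <- logical(nrow(universe))
    for (a in anchors) {
      if (sum(taken) >= n_induced) break
      if (taken[a]) next
      same <- which(universe$chrom == universe$chrom[a] & !taken &
                      abs(universe$canonical_tss - universe$canonical_tss[a]) <= clumping$clump_spread)
      if (length(same) < clumping$clump_size) next
      d <- abs(universe$canonical_tss[same] - universe$canonical_tss[a])
      taken[same[order(d)][seq_len(clumping$clump_size)]] <- TRUE
    }
    short <- n_induced - sum(taken)
    if (short > 0) taken[sample(which(!taken), short)] <- TRUE
    w <- which(taken)
    if (length(w) > n_induced) w <- sort(sample(w, n_induced)) else w
  })
  out <- universe[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a synthetic fixture to disk in the pipeline's input formats
#'
#' Emits a refGene-format annotation (one transcript per TSS), the induced
#' gene TSV (symbol, fold_change), BED files for peaks, TADs and motifs when
#' present, and a JSON truth file.
#'
#' @param truth An `epromoter_truth` from [plant_clusters()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_fixture <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(annotation = file.path(dir, "annotation.refGene.txt"),
                induced = file.path(dir, "induced_genes.tsv"),
                peaks = file.path(dir, "peaks.bed"),
                truth = file.path(dir, "truth.json"))
  g <- truth$genes
  tx_rows <- list()
  acc <- 0L
  for (i in seq_len(nrow(g))) {
    for (tss in g$all_tss[[i]]) {
      acc <- acc + 1L
      if (g$strand[i] == "+") {
        s <- tss; e <- tss + 1500
      } else {
        e <- tss + 1; s <- max(0, tss - 1499)
      }
      tx_rows[[acc]] <- c("0", sprintf("NM_%06d", acc), g$chrom[i], g$strand[i],
                          format(s, scientific = FALSE), format(e, scientific = FALSE),
                          format(s, scientific = FALSE), format(e, scientific = FALSE),
                          "1", paste0(format(s, scientific = FALSE), ","),
                          paste0(format(e, scientific = FALSE), ","),
                          "0", g$symbol[i], "cmpl", "cmpl", "0,")
    }
  }
  writeLines(vapply(tx_rows, paste, "", collapse = "\t"), paths$annotation)
  utils::write.table(truth$induced, paths$induced, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("symbol", "fold_change"))
  write_bed(truth$peaks, paths$peaks)
  if (!is.null(truth$tads)) {
    paths$tads <- file.path(dir, "tads.bed")
    write_bed(truth$tads, paths$tads)
  }
  if (!is.null(truth$motif_track)) {
    paths$motifs <- file.path(dir, "motifs.bed")
    write_bed(truth$motif_track, paths$motifs)
  }
  jsonlite::write_json(list(
    seed = truth$seed, params = truth$params,
    induced = truth$induced, singletons = truth$singletons,
    clusters = lapply(truth$clusters, function(cl) cl[c("members", "epromoters", "coinduced", "chrom")])
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}
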