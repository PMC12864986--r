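# Pipeline orchestration: resolve inputs, reconcile chromosome naming, run
# annotation -> clustering -> Epromoter calling -> summaries, write the two
# standard output files per method, and aggregate across datasets.

resolve_genes <- function(annotation, coding_only = TRUE) {
  if (is.character(annotation)) {
    return(collapse_genes(load_annotation(annotation, coding_only = coding_only)))
  }
  if (is_gene_table(annotation)) return(annotation)
  if (is.data.frame(annotation)) return(collapse_genes(annotation))
  stop("annotation must be a file path, a transcript table, or a gene table")
}

resolve_intervals <- function(x, target_style) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) x <- read_bed(x)
  x$chrom <- normalize_chrom_style(x$chrom, target_style)
  x
}

#' Run the Epromoter-detection pipeline on one dataset
#'
#' Consumes the three standard inputs — an induced-gene list with fold
#' changes, TF ChIP-seq peaks, and a refGene annotation — plus optional TADs,
#' and produces, per clustering method, the clusters, the classified calls,
#' the dataset summary, and the two standard output tables: (1) gene clusters
#' with per-TF binding information and (2) Epromoter-regulated clusters with
#' their epromoter and co-induced genes. Chromosome naming of peak/TAD inputs
#' is normalized to the annotation's convention. Induced symbols absent from
#' the annotation are counted and reported, not fatal.
#'
#' @param annotation refGene file path, transcript table, or gene table.
#' @param induced Induced-gene TSV path or `data.frame` (`symbol`,
#'   `fold_change`).
#' @param peaks A peak BED path / interval table, or a named list of them
#'   (one per TF; binding is OR-combined across TFs).
#' @param tads Optional TAD BED path or interval table (required for the
#'   `"tad"` method).
#' @param dataset_id Dataset identifier used in cluster ids and outputs.
#' @param genome_build Genome build label (for cross-dataset merging).
#' @param methods Clustering methods to run: subset of
#'   `c("distance", "tad")`.
#' @param max_gap Distance-clustering TSS gap threshold in bp (exclusive;
#'   default 100,000).
#' @param flank Promoter half-width in bp (default 1000).
#' @param criterion Epromoter criterion per method; `NULL` uses the defaults
#'   (`fewer_than_n` for distance clusters, `exactly_one` for TAD clusters).
#'   A single value applies to all methods.
#' @param coding_only Restrict the annotation to protein-coding transcripts.
#' @param smallest_tad_only Assign genes only to their smallest containing
#'   TAD.
#' @param out_dir Optional output directory; when given, writes per-method
#'   `clusters_with_tf_binding_<method>.tsv`,
#'   `epromoter_clusters_<method>.tsv`, `summary_<method>.json`,
#'   `bubble_grid_<method>.tsv`, a `run.log`, and the resolved `config.json`.
#' @return A list of class `epromoter_run`: `genes`, `induced_genes`,
#'   `missing_symbols`, `config`, and per-method results under `$results`
#'   (each with `clusters`, `calls`, `summary`, `bubble`, `binding`).
#' @export
run_epromoter_pipeline <- function(annotation, induced, peaks, tads = NULL,
                                   dataset_id = "dataset",
                                   genome_build = "custom",
                                   methods = c("distance", "tad"),
                                   max_gap = 100000, flank = 1000,
                                   criterion = NULL, coding_only = TRUE,
                                   smallest_tad_only = FALSE, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  genes <- resolve_genes(annotation, coding_only = coding_only)
  style <- detect_chrom_style(genes$chrom)
  if (is.character(induced)) induced <- read_induced_genes(induced)
  if (nrow(induced) == 0L) stop("empty induced-gene list")
  if (is.data.frame(peaks) || is.character(peaks)) peaks <- list(TF = peaks)
  if (is.null(names(peaks)) || any(!nzchar(names(peaks)))) {
    names(peaks) <- sprintf("TF%d", seq_along(peaks))
  }
  peaks <- lapply(peaks, resolve_intervals, target_style = style)
  tads <- resolve_intervals(tads, style)
  if ("tad" %in% methods && is.null(tads)) {
    stop("the 'tad' clustering method requires a TAD interval input")
  }

  missing <- setdiff(induced$symbol, genes$symbol)
  if (length(missing)) {
    message(sprintf("%d induced symbol(s) absent from the annotation (kept out of the analysis)",
                    length(missing)))
  }
  matched <- induced[induced$symbol %in% genes$symbol, , drop = FALSE]
  if (nrow(matched) == 0L) stop("no induced gene matches the annotation")
  induced_genes <- genes[match(matched$symbol, genes$symbol), , drop = FALSE]
  induced_genes$fold_change <- matched$fold_change
  induced_genes <- induced_genes[order(induced_genes$chrom, induced_genes$canonical_tss,
                                       induced_genes$symbol), , drop = FALSE]
  rownames(induced_genes) <- NULL

  results <- list()
  log_lines <- c(sprintf("dataset %s (%s); %d induced symbols, %d matched, %d missing",
                         dataset_id, genome_build, nrow(induced), nrow(matched),
                         length(missing)))
  for (m in methods) {
    clusters <- if (m == "distance") {
      cluster_by_distance(induced_genes, max_gap = max_gap, dataset_id = dataset_id)
    } else {
      cluster_by_tad(induced_genes, tads, smallest_only = smallest_tad_only,
                     dataset_id = dataset_id)
    }
    crit <- criterion %||% if (m == "distance") "fewer_than_n" else "exactly_one"
    calls <- classify_clusters(clusters, genes, peaks, criterion = crit, flank = flank)
    summ <- summarize_dataset(calls, dataset_id = dataset_id,
                              n_induced_genes = nrow(matched))
    binding <- cluster_binding_table(calls, induced_genes, peaks, flank)
    results[[m]] <- list(clusters = clusters, calls = calls,
                         summary = summ$summary, bubble = summ$bubble,
                         binding = binding, criterion = crit)
    log_lines <- c(log_lines, sprintf(
      "method %s (%s): %d clusters (%d genes), %d epromoter_regulated, %d all_bound, %d unbound, %d partial_multi",
      m, crit, summ$summary$n_clusters, summ$summary$n_genes_in_clusters,
      summ$summary$n_epromoter_clusters, summ$summary$n_all_bound_clusters,
      summ$summary$n_unbound_clusters, summ$summary$n_partial_multi_clusters))
  }

  config <- list(dataset_id = dataset_id, genome_build = genome_build,
                 methods = methods, max_gap = max_gap, flank = flank,
                 criterion = lapply(results, `[[`, "criterion"),
                 coding_only = coding_only, smallest_tad_only = smallest_tad_only,
                 tf_labels = names(peaks))
  out <- structure(list(genes = genes, induced_genes = induced_genes,
                        missing_symbols = missing, results = results,
                        config = config, log = log_lines),
                   class = "epromoter_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.epromoter_run <- function(x, ...) {
  cat(sprintf("epromoter_run '%s'\n", x$config$dataset_id))
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

# output file 1: one row per cluster gene with the per-TF bound flags
cluster_binding_table <- function(calls, induced_genes, peaks, flank = 1000) {
  if (nrow(calls) == 0L) {
    return(data.frame(cluster_id = character(0), method = character(0),
                      gene_symbol = character(0), chrom = character(0),
                      tss = numeric(0), fold_change = numeric(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  syms <- unique(unlist(calls$genes))
  sub <- induced_genes[match(syms, induced_genes$symbol), , drop = FALSE]
  bt <- bound_table(sub, peaks, flank)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    gs <- calls$genes[[i]]
    j <- match(gs, sub$symbol)
    cbind(data.frame(cluster_id = calls$cluster_id[i], method = calls$method[i],
                     gene_symbol = gs, chrom = calls$chrom[i],
                     tss = sub$canonical_tss[j],
                     fold_change = sub$fold_change[j] %||% NA_real_,
                     category = calls$category[i], stringsAsFactors = FALSE),
          bt[j, -1L, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# output file 2: Epromoter-regulated clusters only
epromoter_cluster_table <- function(calls) {
  ep <- calls[calls$category == "epromoter_regulated", , drop = FALSE]
  data.frame(
    cluster_id = ep$cluster_id, method = ep$method, chrom = ep$chrom,
    span_start = ep$span_start, span_end = ep$span_end,
    n_genes = ep$n_genes, n_bound = ep$n_bound,
    epromoter_genes = vapply(ep$epromoter_genes, paste, "", collapse = ";"),
    coinduced_genes = vapply(ep$coinduced_genes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(run$results)) {
    res <- run$results[[m]]
    write_tsv6(res$binding, file.path(out_dir, sprintf("clusters_with_tf_binding_%s.tsv", m)))
    write_tsv6(epromoter_cluster_table(res$calls),
               file.path(out_dir, sprintf("epromoter_clusters_%s.tsv", m)))
    write_tsv6(res$bubble, file.path(out_dir, sprintf("bubble_grid_%s.tsv", m)))
    jsonlite::write_json(as.list(res$summary),
                         file.path(out_dir, sprintf("summary_%s.json", m)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Aggregate Epromoter results across datasets
#'
#' Pools per-dataset summaries and calls: the per-dataset frequency table,
#' the pooled bubble grid, the one-bound and fewer-bound shares over all
#' pooled clusters with TF binding, the mean number of Epromoter-regulated
#' clusters per dataset, and the non-redundant merged cluster total
#' ([merge_nonredundant()], grouped by genome build).
#'
#' @param runs A list of `epromoter_run` objects (or of lists with `summary`
#'   and `calls` plus `dataset_id`/`genome_build`).
#' @param method Which method's results to aggregate (default `"distance"`).
#' @return A list with `per_dataset`, `pooled_bubble`, `one_bound_share`,
#'   `fewer_bound_share`, `mean_epromoter_clusters`, `nonredundant`.
#' @export
aggregate_datasets <- function(runs, method = "distance") {
  stopifnot(length(runs) >= 1L)
  summaries <- list()
  calls_all <- list()
  ep_for_merge <- list()
  for (run in runs) {
    res <- run$results[[method]]
    if (is.null(res)) stop("run lacks results for method: ", method)
    summaries[[length(summaries) + 1L]] <- res$summary
    calls <- res$calls
    calls_all[[length(calls_all) + 1L]] <- calls
    ep <- calls[calls$category == "epromoter_regulated", , drop = FALSE]
    if (nrow(ep)) {
      ep_for_merge[[length(ep_for_merge) + 1L]] <- data.frame(
        dataset_id = res$summary$dataset_id,
        genome_build = run$config$genome_build %||% "custom",
        cluster_id = ep$cluster_id, genes = I(ep$genes),
        stringsAsFactors = FALSE
      )
    }
  }
  per_dataset <- do.call(rbind, summaries)
  pooled <- do.call(rbind, calls_all)
  with_binding <- pooled$n_bound >= 1L
  nb <- sum(with_binding)
  pooled_grid <- stats::aggregate(list(n_clusters = rep(1L, nrow(pooled))),
                                  by = list(n_genes = pooled$n_genes,
                                            n_bound = pooled$n_bound), FUN = sum)
  merged <- merge_nonredundant(
    if (length(ep_for_merge)) do.call(rbind, ep_for_merge)
    else data.frame(dataset_id = character(0), genome_build = character(0),
                    cluster_id = character(0), genes = I(list())))
  list(
    per_dataset = per_dataset,
    pooled_bubble = pooled_grid[order(pooled_grid$n_genes, pooled_grid$n_bound), ],
    one_bound_share = if (nb) sum(pooled$n_bound[with_binding] == 1L) / nb else NA_real_,
    fewer_bound_share = if (nb) {
      sum(pooled$n_bound[with_binding] < pooled$n_genes[with_binding]) / nb
    } else NA_real_,
    mean_epromoter_clusters = mean(per_dataset$n_epromoter_clusters),
    nonredundant = merged
  )
}
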