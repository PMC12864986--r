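# Gene annotation: UCSC refGene parsing, transcript-to-gene collapse, and
# promoter window construction.
#
# Coordinate conventions follow UCSC: txStart is 0-based, txEnd exclusive.
# The TSS of a "+" transcript is txStart; the TSS of a "-" transcript is
# txEnd - 1 (the last genomic base of the half-open interval).

#' Load a UCSC refGene annotation
#'
#' Reads a tab-separated annotation in UCSC refGene column order
#' (bin, name, chrom, strand, txStart, txEnd, ..., name2, ...), as distributed
#' for hg19/hg38/mm9/mm10. Rows on unplaced or alternative contigs (chromosome
#' names containing `_`) are always dropped; with `coding_only = TRUE` only
#' protein-coding accessions (`NM_` prefix) are kept.
#'
#' @param path Path to a refGene `.txt` or `.txt.gz` file.
#' @param dialect Annotation dialect; only `"refGene"` is supported.
#' @param coding_only Keep protein-coding (`NM_`) transcripts only. Default
#'   `TRUE`: the analysis considers protein-coding genes.
#' @return A `data.frame` of transcript records with columns `transcript_id`,
#'   `gene_symbol`, `chrom`, `strand`, `tx_start`, `tx_end`, `is_coding`.
#' @seealso [collapse_genes()] to reduce transcripts to per-gene TSS models.
#' @export
load_annotation <- function(path, dialect = c("refGene"), coding_only = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 13L)
  if (length(bad)) {
    stop(sprintf("malformed annotation row at line %d: expected >= 13 tab-separated fields, found %d",
                 bad[1L], nf[bad[1L]]))
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  tx <- data.frame(
    transcript_id = get(2L),
    gene_symbol   = get(13L),
    chrom         = get(3L),
    strand        = get(4L),
    tx_start      = suppressWarnings(as.numeric(get(5L))),
    tx_end        = suppressWarnings(as.numeric(get(6L))),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(tx$tx_start) | is.na(tx$tx_end) | tx$tx_start >= tx$tx_end |
                 !(tx$strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("malformed annotation row at line %d: invalid coordinates or strand", bad[1L]))
  }
  tx$is_coding <- grepl("^NM_", tx$transcript_id)
  tx <- tx[!grepl("_", tx$chrom, fixed = TRUE), , drop = FALSE]
  if (coding_only) tx <- tx[tx$is_coding, , drop = FALSE]
  if (nrow(tx) == 0L) stop("annotation is empty after filtering: ", path)
  rownames(tx) <- NULL
  tx
}

#' Collapse transcripts into gene models
#'
#' Groups transcript records by gene symbol and derives, per gene, the set of
#' all alternative TSSs and a single canonical TSS used for distances and
#' clustering. The TSS is strand-aware (`tx_start` for `+`, `tx_end - 1` for
#' `-`); the canonical TSS is the 5'-most TSS in the direction of
#' transcription (minimum coordinate on `+`, maximum on `-`). Genes whose
#' transcripts disagree on chromosome or strand are emitted on the
#' chromosome/strand of their longest transcript and reported via `message()`.
#'
#' @param transcripts A transcript `data.frame` as returned by
#'   [load_annotation()].
#' @return A gene `data.frame` with columns `symbol`, `chrom`, `strand`,
#'   `canonical_tss`, `is_coding` and a list-column `all_tss`, sorted by
#'   chromosome and canonical TSS. The result is independent of the input
#'   transcript order and idempotent under re-collapse of its own rows.
#' @export
collapse_genes <- function(transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L) stop("no transcripts to collapse")
  groups <- split(transcripts, transcripts$gene_symbol)
  conflicts <- character(0)
  rows <- lapply(groups, function(g) {
    key <- paste(g$chrom, g$strand)
    if (length(unique(key)) > 1L) {
      conflicts <<- c(conflicts, g$gene_symbol[1L])
      longest <- which.max(g$tx_end - g$tx_start)
      g <- g[key == key[longest], , drop = FALSE]
    }
    tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1)
    all_tss <- sort(unique(tss))
    canonical <- if (g$strand[1L] == "+") min(all_tss) else max(all_tss)
    data.frame(
      symbol = g$gene_symbol[1L], chrom = g$chrom[1L], strand = g$strand[1L],
      canonical_tss = canonical, is_coding = any(g$is_coding),
      all_tss = I(list(all_tss)), stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, rows)
  if (length(conflicts)) {
    message("collapse_genes: ", length(conflicts),
            " gene(s) with conflicting chrom/strand resolved to the longest transcript: ",
            paste(sort(unique(conflicts)), collapse = ", "))
  }
  genes <- genes[order(genes$chrom, genes$canonical_tss, genes$symbol), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

# collapse_genes() input can also be a gene table already; detect by columns
is_gene_table <- function(x) {
  is.data.frame(x) && all(c("symbol", "chrom", "strand", "canonical_tss", "all_tss") %in% names(x))
}

#' Build promoter windows around TSSs
#'
#' Emits half-open promoter windows anchored at each gene's TSS(s). Windows
#' are inclusive of both flanks around the anchor base: with
#' `upstream = downstream = 1000` a `+`-strand TSS at 10,000 yields
#' `[9000, 11001)`, i.e. the 1 kb on either side plus the TSS base itself
#' (the "+/- 1 kb" promoter-proximal region). With `strand_aware = TRUE` the
#' upstream flank is placed against the direction of transcription, which
#' matters for asymmetric windows such as the -1250/+750 bp motif-counting
#' window.
#'
#' @param genes Gene table from [collapse_genes()].
#' @param upstream,downstream Flank sizes in bp (>= 0).
#' @param per_tss One window per alternative TSS (`TRUE`, default) or a single
#'   window at the canonical TSS.
#' @param strand_aware Orient the flanks by strand; irrelevant for symmetric
#'   windows.
#' @return A `data.frame` with columns `gene_symbol`, `chrom`, `start`, `end`,
#'   `anchor_tss`, `strand`; starts are clamped at 0.
#' @export
promoter_windows <- function(genes, upstream = 1000, downstream = 1000,
                             per_tss = TRUE, strand_aware = TRUE) {
  stopifnot(upstream >= 0, downstream >= 0)
  tss_list <- if (per_tss) genes$all_tss else as.list(genes$canonical_tss)
  n_per <- lengths(tss_list)
  tss <- unlist(tss_list, use.names = FALSE)
  strand <- rep(genes$strand, n_per)
  symbol <- rep(genes$symbol, n_per)
  chrom <- rep(genes$chrom, n_per)
  minus <- strand_aware & strand == "-"
  start <- ifelse(minus, tss - downstream, tss - upstream)
  end <- ifelse(minus, tss + upstream + 1, tss + downstream + 1)
  data.frame(
    gene_symbol = symbol, chrom = chrom,
    start = pmax(0, start), end = end,
    anchor_tss = tss, strand = strand, stringsAsFactors = FALSE
  )
}

#' Write collapsed genes as a BED6 of canonical TSS points
#'
#' @param genes Gene table from [collapse_genes()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, format(genes$canonical_tss, scientific = FALSE, trim = TRUE),
                    format(genes$canonical_tss + 1, scientific = FALSE, trim = TRUE),
                    genes$symbol, 0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
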