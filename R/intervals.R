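# Deterministic genomic-interval primitives with bedtools-compatible
# contracts: nearest-feature distance with ignore-overlap, per-query overlap
# counting, and interval extension (slop). Overlap counting is delegated to
# GenomicRanges::countOverlaps after conversion from the package's 0-based
# half-open convention to 1-based closed ranges.

#' Nearest-neighbour distances between genomic points
#'
#' For each point, the distance in bp to the closest *other* point on the same
#' chromosome, excluding points at the identical coordinate — the contract of
#' `bedtools closest -d -io -t first` applied to 1-bp features, except that
#' distances are plain `|a - b|` between point coordinates rather than the
#' bedtools edge gap. Points alone on their chromosome, or whose only
#' companions are co-located, are absent from the result.
#'
#' @param points A `data.frame` with columns `chrom`, `pos` and `id`.
#' @return A named numeric vector of distances, names taken from `id`; ids
#'   without an eligible neighbour are absent.
#' @export
nearest_other_point <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("chrom", "pos", "id") %in% names(points)))
  out <- numeric(0)
  for (chr in unique(points$chrom)) {
    p <- points[points$chrom == chr, , drop = FALSE]
    u <- sort(unique(p$pos))
    if (length(u) < 2L) next
    gap_left <- c(Inf, diff(u))
    gap_right <- c(diff(u), Inf)
    nearest <- pmin(gap_left, gap_right)
    d <- nearest[match(p$pos, u)]
    names(d) <- p$id
    out <- c(out, d)
  }
  out
}

#' Count overlapping subject intervals per query
#'
#' The contract of `bedtools intersect -c`: for each query interval, the number
#' of subject intervals sharing at least 1 bp under half-open semantics.
#'
#' @param queries,subjects Interval `data.frame`s (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @return Integer vector of counts, one per query row.
#' @export
count_overlaps <- function(queries, subjects) {
  if (nrow(queries) == 0L) return(integer(0))
  if (is.null(subjects) || nrow(subjects) == 0L) return(integer(nrow(queries)))
  q <- intervals_to_granges(queries)
  s <- intervals_to_granges(subjects)
  # put both on the union of seqlevels (inputs may cover disjoint chromosomes)
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  GenomicRanges::countOverlaps(q, s)
}

#' Extend intervals symmetrically (slop)
#'
#' @param intervals Interval `data.frame`, 0-based half-open.
#' @param pad Extension in bp on each side (>= 0).
#' @param chrom_len Optional named vector (or single value) of chromosome
#'   lengths to clamp the right edge; the left edge is always clamped at 0.
#' @return The extended interval `data.frame`.
#' @export
extend_intervals <- function(intervals, pad, chrom_len = NULL) {
  stopifnot(pad >= 0)
  out <- intervals
  out$start <- pmax(0, intervals$start - pad)
  out$end <- intervals$end + pad
  if (!is.null(chrom_len)) {
    lim <- if (is.null(names(chrom_len))) rep(chrom_len, nrow(out))
           else unname(chrom_len[out$chrom])
    out$end <- pmin(out$end, lim)
  }
  out
}

#' Read a BED3/BED6 file into an interval table
#'
#' Tolerates `track`, `browser` and `#` header lines (handled by
#' `rtracklayer`). Coordinates come back in the package's 0-based half-open
#' convention; a `name` column is kept when present.
#'
#' @param path Path to a BED file.
#' @param chrom_style `"asis"` (default), `"ucsc"` or `"plain"`; see
#'   [normalize_chrom_style()].
#' @return An interval `data.frame` (`chrom`, `start`, `end`, optionally
#'   `name`).
#' @export
read_bed <- function(path, chrom_style = c("asis", "ucsc", "plain")) {
  chrom_style <- match.arg(chrom_style)
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = normalize_chrom_style(as.character(GenomicRanges::seqnames(gr)), chrom_style),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- as.character(nm)
  out
}

#' Write an interval table as BED
#'
#' @param intervals Interval `data.frame` (0-based half-open, matching BED).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- data.frame(intervals$chrom,
                     format(intervals$start, scientific = FALSE, trim = TRUE),
                     format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) cols$name <- intervals$name
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
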