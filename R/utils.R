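# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open [start, end); conversion to the 1-based closed
# convention happens only at the IRanges/GenomicRanges boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` with a private RNG stream seeded at `seed`, restoring the caller's
# RNG state afterwards. Every source of randomness in the package flows through
# an explicit seed argument; there is no hidden global seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open, the convention of the BED format.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `start < end`, `start >= 0`.
#' @param name Optional character vector of interval names.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when given,
#'   `name`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- as.character(name)
  out
}

# 0-based half-open data.frame -> 1-based closed GRanges
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Normalize chromosome naming style
#'
#' Maps between the UCSC ("chr1") and plain ("1") chromosome naming styles so
#' that peak, TAD and motif inputs can be reconciled with the annotation.
#'
#' @param chroms Character vector of chromosome names.
#' @param style `"ucsc"` to add the `chr` prefix, `"plain"` to strip it,
#'   `"asis"` to leave names untouched.
#' @return Character vector of renamed chromosomes.
#' @export
normalize_chrom_style <- function(chroms, style = c("asis", "ucsc", "plain")) {
  style <- match.arg(style)
  chroms <- as.character(chroms)
  if (style == "ucsc") {
    ifelse(startsWith(chroms, "chr"), chroms, paste0("chr", chroms))
  } else if (style == "plain") {
    sub("^chr", "", chroms)
  } else {
    chroms
  }
}

detect_chrom_style <- function(chroms) {
  if (any(startsWith(as.character(chroms), "chr"))) "ucsc" else "plain"
}

# write a TSV with a fixed column order; floats at 6 significant digits
write_tsv6 <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], paste, "", collapse = ";")
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
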