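# Proximity statistics: do induced genes sit closer together than random
# genes? Nearest-TSS distance samples, seeded random nulls, two-sample K-S
# comparison, the signed Q-Q deviation score, the distance-distribution
# summit, and fractions within a distance threshold.

#' Nearest-TSS distance sample for a gene set
#'
#' Computes, for every gene, the distance from its canonical TSS to the
#' closest other gene's canonical TSS on the same chromosome (ignoring
#' co-located TSSs). Genes with no eligible neighbour are excluded and
#' counted.
#'
#' @param genes Gene table ([collapse_genes()]); at least 2 rows.
#' @param label Free-text label stored with the sample.
#' @return An object of class `distance_sample`: a list with `label`,
#'   `distances` (bp, all > 0), `n_genes_input`, `n_excluded_singletons`.
#' @export
nn_distances <- function(genes, label = "genes") {
  if (is.null(genes) || nrow(genes) < 2L) {
    stop("nn_distances requires at least 2 genes")
  }
  d <- nearest_other_point(data.frame(
    chrom = genes$chrom, pos = genes$canonical_tss, id = genes$symbol,
    stringsAsFactors = FALSE
  ))
  distance_sample(unname(d), label = label, n_genes_input = nrow(genes))
}

#' @rdname nn_distances
#' @param distances Numeric vector of pairwise-nearest distances in bp (> 0).
#' @param n_genes_input Number of genes the distances were derived from.
#' @export
distance_sample <- function(distances, label = "sample",
                            n_genes_input = length(distances)) {
  distances <- as.numeric(distances)
  if (any(distances <= 0)) stop("distances must be > 0")
  if (length(distances) > n_genes_input) stop("more distances than input genes")
  structure(
    list(label = label, distances = distances,
         n_genes_input = as.integer(n_genes_input),
         n_excluded_singletons = as.integer(n_genes_input - length(distances))),
    class = "distance_sample"
  )
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("distance_sample '%s': %d distances from %d genes (%d excluded singletons)\n",
              x$label, length(x$distances), x$n_genes_input, x$n_excluded_singletons))
  if (length(x$distances)) {
    cat(sprintf("  median %.1f kb, range %.1f-%.1f kb\n",
                stats::median(x$distances) / 1000,
                min(x$distances) / 1000, max(x$distances) / 1000))
  }
  invisible(x)
}

as_distances <- function(x) {
  if (inherits(x, "distance_sample")) x$distances else as.numeric(x)
}

#' Draw a random gene null set
#'
#' Uniform sample without replacement from a gene universe, matching the size
#' of an induced set; the null model for the proximity statistics. The same
#' seed always reproduces the same sample, and the caller's RNG state is left
#' untouched.
#'
#' @param universe Gene table to sample from (typically all protein-coding
#'   genes of the annotation).
#' @param n Number of genes to draw (`n <= nrow(universe)`).
#' @param seed Integer seed; required.
#' @return A gene table of `n` rows, sorted like [collapse_genes()] output.
#' @export
random_gene_null <- function(universe, n, seed) {
  if (n > nrow(universe)) {
    stop(sprintf("cannot draw %d genes from a universe of %d", n, nrow(universe)))
  }
  idx <- with_seed(seed, sample.int(nrow(universe), n))
  out <- universe[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of distance samples
#'
#' @param a,b `distance_sample` objects or numeric vectors; non-empty.
#' @return A list with `statistic` (the K-S D in `[0, 1]`) and `p_value`
#'   (two-sided).
#' @export
ks_compare <- function(a, b) {
  da <- as_distances(a)
  db <- as_distances(b)
  if (length(da) == 0L || length(db) == 0L) stop("ks_compare: empty distance sample")
  kt <- suppressWarnings(stats::ks.test(da, db, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

qq_quantiles <- function(x, n_quantiles) {
  p <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  stats::quantile(x, probs = p, names = FALSE, type = 7)
}

#' Signed Q-Q deviation score between two distance distributions
#'
#' Both samples are reduced to `n_quantiles` linear-interpolation quantiles at
#' probabilities `(k - 0.5) / K`; each Q-Q point (random on x, induced on y)
#' contributes its signed Euclidean distance to the identity line `y = x`,
#' i.e. `(q_induced - q_random) / sqrt(2)`, and the score is the sum of these
#' contributions. Negative scores mean the induced genes lie closer together
#' than the random ones.
#'
#' @param induced,random `distance_sample` objects or numeric vectors.
#' @param n_quantiles Number of Q-Q quantile points (default 1000).
#' @param units Report the score in `"kb"` (default) or `"bp"`.
#' @param summary `"sum"` (default) or `"mean"` (sum divided by
#'   `n_quantiles`), for a per-quantile-point average on the same scale.
#' @return A single signed number.
#' @export
deviation_score <- function(induced, random, n_quantiles = 1000,
                            units = c("kb", "bp"), summary = c("sum", "mean")) {
  units <- match.arg(units)
  summary <- match.arg(summary)
  di <- as_distances(induced)
  dr <- as_distances(random)
  if (length(di) == 0L || length(dr) == 0L) stop("deviation_score: empty distance sample")
  qi <- qq_quantiles(di, n_quantiles)
  qr <- qq_quantiles(dr, n_quantiles)
  score <- sum(qi - qr) / sqrt(2)
  if (units == "kb") score <- score / 1000
  if (summary == "mean") score <- score / n_quantiles
  score
}

#' Per-quantile Q-Q table for plotting
#'
#' @inheritParams deviation_score
#' @return A `data.frame` with `p`, `q_random`, `q_induced` and the signed
#'   per-point deviation `dev` (input units / sqrt(2)).
#' @export
qq_table <- function(induced, random, n_quantiles = 1000) {
  di <- as_distances(induced)
  dr <- as_distances(random)
  if (length(di) == 0L || length(dr) == 0L) stop("qq_table: empty distance sample")
  qi <- qq_quantiles(di, n_quantiles)
  qr <- qq_quantiles(dr, n_quantiles)
  data.frame(p = (seq_len(n_quantiles) - 0.5) / n_quantiles,
             q_random = qr, q_induced = qi, dev = (qi - qr) / sqrt(2))
}

#' Summit (mode) of a nearest-TSS distance distribution
#'
#' Distances are log10-transformed, a Gaussian kernel density with a
#' normal-reference (Scott-type) bandwidth is evaluated on a 512-point grid
#' spanning the data, and the summit is the back-transformed argmax, reported
#' in kb. Matches the log-scaled density displays the summit values are read
#' from.
#'
#' @param sample A `distance_sample` or numeric vector of >= 10 distances (bp).
#' @return The summit in kb.
#' @export
distribution_summit <- function(sample) {
  d <- as_distances(sample)
  if (length(d) < 10L) stop("distribution_summit needs >= 10 distances")
  lx <- log10(d)
  if (diff(range(lx)) == 0) return(10^lx[1L] / 1000)
  bw <- tryCatch(stats::bw.nrd(lx), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) {
    bw <- max(1.06 * stats::sd(lx) * length(lx)^(-1 / 5), 1e-6)
  }
  dens <- stats::density(lx, bw = bw, n = 512, from = min(lx), to = max(lx))
  10^(dens$x[which.max(dens$y)]) / 1000
}

#' Fraction of distances within a threshold
#'
#' Share of nearest-TSS distances less than or equal to `threshold`
#' (boundary inclusive). Default threshold 100 kb, the cluster distance rule.
#'
#' @param sample A `distance_sample` or numeric vector.
#' @param threshold Distance threshold in bp.
#' @return A fraction in `[0, 1]`; 0 for an empty sample.
#' @export
fraction_within <- function(sample, threshold = 100000) {
  d <- as_distances(sample)
  if (length(d) == 0L) return(0)
  mean(d <= threshold)
}

#' Full proximity report for an induced gene set
#'
#' Draws a random null of the same size from the universe, computes both
#' nearest-TSS distance samples, and assembles the K-S comparison, deviation
#' score (sum and per-quantile mean), distribution summits, and
#' within-threshold fractions.
#'
#' @param induced Gene table of induced genes (>= 2 rows).
#' @param universe Gene table to draw the random null from.
#' @param n_quantiles Q-Q quantile points for the deviation score.
#' @param threshold Distance threshold in bp for [fraction_within()].
#' @param seed Integer seed for the random null; required.
#' @param label Label for the induced sample.
#' @return A list of class `proximity_report` with the statistics plus the two
#'   `distance_sample`s.
#' @export
proximity_report <- function(induced, universe, n_quantiles = 1000,
                             threshold = 100000, seed, label = "induced") {
  si <- nn_distances(induced, label = label)
  null_genes <- random_gene_null(universe, nrow(induced), seed)
  sr <- nn_distances(null_genes, label = "random")
  ks <- ks_compare(si, sr)
  structure(list(
    label = label,
    ks_statistic = ks$statistic,
    ks_pvalue = ks$p_value,
    deviation_score = deviation_score(si, sr, n_quantiles, units = "kb"),
    deviation_score_mean = deviation_score(si, sr, n_quantiles, units = "kb",
                                           summary = "mean"),
    summit_induced = distribution_summit(si),
    summit_random = distribution_summit(sr),
    frac_within_threshold_induced = fraction_within(si, threshold),
    frac_within_threshold_random = fraction_within(sr, threshold),
    n_quantiles = as.integer(n_quantiles),
    threshold = threshold,
    seed = as.integer(seed),
    induced_sample = si,
    random_sample = sr
  ), class = "proximity_report")
}

#' @export
print.proximity_report <- function(x, ...) {
  cat(sprintf("proximity_report '%s'\n", x$label))
  cat(sprintf("  K-S D = %.4f, p = %.3g\n", x$ks_statistic, x$ks_pvalue))
  cat(sprintf("  deviation score = %.2f kb (per-quantile mean %.4f kb)\n",
              x$deviation_score, x$deviation_score_mean))
  cat(sprintf("  summit: induced %.1f kb vs random %.1f kb\n",
              x$summit_induced, x$summit_random))
  cat(sprintf("  within %.0f kb: induced %.1f%% vs random %.1f%%\n",
              x$threshold / 1000, 100 * x$frac_within_threshold_induced,
              100 * x$frac_within_threshold_random))
  invisible(x)
}

#' Read an induced-gene list (symbol + fold change TSV)
#'
#' @param path Two-column tab-separated file with a header; first column gene
#'   symbol, second fold change.
#' @return A `data.frame` with columns `symbol`, `fold_change`.
#' @export
read_induced_genes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("induced-gene file must have 2 columns (symbol, fold_change): ", path)
  out <- data.frame(symbol = as.character(df[[1L]]),
                    fold_change = as.numeric(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("induced-gene list is empty: ", path)
  out
}
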