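#' Reads per kilobase of exon per million mapped reads
#'
#' `rpkm(g, s) = counts(g, s) * 1e9 / (length(g) * total(s))`.  By default the
#' per-sample total is the column sum of the supplied matrix; when the totals
#' used for normalization should come from a larger alignment (e.g. all
#' mapped reads rather than reads in the matrix), pass them explicitly.
#'
#' @param counts A [count_matrix()].
#' @param totals Optional named (or column-ordered) vector of per-sample
#'   total mapped reads overriding the column sums.
#' @return An [expr_matrix()] at stage `"rpkm"`.
#' @export
compute_rpkm <- function(counts, totals = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (is.null(totals)) totals <- colSums(m)
  else if (!is.null(names(totals))) totals <- totals[colnames(m)]
  if (length(totals) != ncol(m) || anyNA(totals))
    stop("totals must provide one value per sample")
  zero <- totals <= 0
  if (any(zero))
    stop("zero total mapped reads for sample(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  v <- m * 1e9 / outer(counts$gene_lengths, totals)
  expr_matrix(v, "rpkm")
}

#' Filter genes by detectable expression
#'
#' Default mode keeps genes with RPKM strictly greater than `min_rpkm` in
#' strictly more than `min_fraction` of samples.  `mode = "nonzero"` applies
#' only the weaker rule that expression is not zero across all samples.
#'
#' @param expr An `expr_matrix` at stage `"rpkm"`.
#' @param min_rpkm RPKM threshold (strict).
#' @param min_fraction Fraction-of-samples threshold (strict).
#' @param mode `"threshold"` (default) or `"nonzero"`.
#' @return The filtered `expr_matrix` (gene order preserved).
#' @export
filter_expressed <- function(expr, min_rpkm = 0.2, min_fraction = 0.75,
                             mode = c("threshold", "nonzero")) {
  mode <- match.arg(mode)
  stopifnot_stage(expr, "rpkm")
  keep <- if (mode == "threshold")
    rowMeans(expr > min_rpkm) > min_fraction
  else
    rowSums(expr != 0) > 0
  if (!any(keep)) warning("no genes pass the expression filter")
  expr_matrix(unclass(expr)[keep, , drop = FALSE], "rpkm")
}

#' Filter genes by a minimum read count in at least one sample
#'
#' @param counts A [count_matrix()].
#' @param min_reads Keep genes whose maximum count across samples is at
#'   least this many reads.
#' @return The filtered [count_matrix()].
#' @export
filter_min_counts <- function(counts, min_reads = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- apply(counts$counts, 1, max) >= min_reads
  count_matrix(counts$counts[keep, , drop = FALSE],
               counts$gene_lengths[keep])
}

#' Upper-quartile normalization of counts
#'
#' Each sample is divided by the 75th percentile of its nonzero counts, then
#' rescaled by the geometric mean of those percentiles so that overall
#' magnitude is preserved.
#'
#' @param counts A [count_matrix()].
#' @return An [expr_matrix()] at stage `"uq_normalized"`.
#' @export
upper_quartile_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  uq <- vapply(seq_len(ncol(m)), function(s) {
    nz <- m[m[, s] > 0, s]
    if (length(nz) == 0)
      stop("sample has no nonzero counts: ", colnames(m)[s])
    stats::quantile(nz, 0.75, names = FALSE)
  }, numeric(1))
  scale_back <- exp(mean(log(uq)))
  v <- sweep(m, 2, uq, "/") * scale_back
  expr_matrix(v, "uq_normalized")
}

#' Log2 transform and per-gene median centering
#'
#' `value = log2(rpkm + pseudocount) - rowmedian(log2(rpkm + pseudocount))`.
#' Entries that were exactly zero RPKM are flagged in a `not_expressed`
#' attribute so display layers can distinguish "not expressed" from low
#' expression.
#'
#' @param expr An `expr_matrix` at stage `"rpkm"`.
#' @param pseudocount Added before taking logs (default 0.01).
#' @return An [expr_matrix()] at stage `"log2_centered"` with attribute
#'   `not_expressed` (logical matrix).
#' @export
log2_median_center <- function(expr, pseudocount = 0.01) {
  stopifnot_stage(expr, "rpkm")
  l <- log2(unclass(expr) + pseudocount)
  med <- apply(l, 1, stats::median)
  out <- expr_matrix(l - med, "log2_centered")
  attr(out, "not_expressed") <- unclass(expr) == 0
  out
}
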