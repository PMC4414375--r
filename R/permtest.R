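#' Principal components of a signature-restricted expression matrix
#'
#' Samples are the observations and the signature genes the variables.
#' Variables are centered but not rescaled (the intended input is already
#' log2 median-centered per gene).  A deterministic sign convention is
#' applied: each component is flipped so its largest-magnitude gene loading
#' is positive.
#'
#' @param expr Expression matrix (genes x samples); an `expr_matrix` or a
#'   plain numeric matrix with gene rownames.
#' @param signature Character vector of gene ids (or integer row indices).
#' @param n_components Number of leading components to return.
#' @return List with `scores` (samples x `n_components`),
#'   `variance_explained` (fraction per component, over all components) and
#'   `loadings` (genes x `n_components`).
#' @export
signature_pca <- function(expr, signature, n_components = 3) {
  m <- unclass(expr)
  if (is.character(signature)) {
    present <- intersect(signature, rownames(m))
    if (length(present) < 2) {
      miss <- setdiff(signature, rownames(m))
      stop("fewer than 2 signature genes present in the matrix; missing: ",
           paste(utils::head(miss, 10), collapse = ", "))
    }
    idx <- match(present, rownames(m))
  } else idx <- signature
  if (ncol(m) < n_components + 1)
    stop("need at least n_components + 1 samples")
  x <- t(m[idx, , drop = FALSE])          # samples x genes
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(m)[idx]
  ve <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, variance_explained = ve, loadings = loadings)
}

# Fast internal kernel: PCA scores (k comps) then Pillai F, given a
# genes x samples matrix already restricted to a gene subset.
# group_idx: list of integer vectors of sample indices per group.
pca_manova_F_kernel <- function(sub, group_idx, n_components = 3) {
  x <- t(sub)
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_components, nv = 0)
  k <- min(n_components, sum(sv$d > sv$d[1] * 1e-12))
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = nrow(x))
  pillai_F(scores, group_idx)
}

pillai_F <- function(scores, group_idx) {
  n <- nrow(scores)
  p <- ncol(scores)
  g <- length(group_idx)
  grand <- colMeans(scores)
  yc <- sweep(scores, 2, grand)
  total <- crossprod(yc)
  h <- matrix(0, p, p)
  for (idx in group_idx) {
    mk <- colMeans(scores[idx, , drop = FALSE]) - grand
    h <- h + length(idx) * tcrossprod(mk)
  }
  e <- total - h
  v <- sum(diag(h %*% solve(total)))
  s <- min(p, g - 1)
  m <- (abs(p - g + 1) - 1) / 2
  nn <- (n - g - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- (df2 / df1) * v / (s - v)
  list(F = f, pillai = v, df1 = df1, df2 = df2)
}

#' One-way MANOVA F statistic (Pillai's trace approximation)
#'
#' Fits the one-way MANOVA of the score columns on the group label and
#' returns the standard F transform of Pillai's trace.
#'
#' @param scores Numeric matrix, samples x responses (typically the first 3
#'   principal component scores).
#' @param groups A factor of group labels, or a [sample_design()] whose
#'   `sample` column matches `rownames(scores)`.
#' @return List with elements `F`, `pillai`, `df1`, `df2`.
#' @export
manova_f <- function(scores, groups) {
  scores <- as.matrix(scores)
  if (inherits(groups, "sample_design"))
    groups <- design_groups(groups, rownames(scores))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 1)) stop("empty group")
  if (nrow(scores) <= nlevels(groups) + 2)
    stop("too few samples for a ", ncol(scores), "-response MANOVA")
  group_idx <- split(seq_len(nrow(scores)), groups)
  res <- tryCatch(pillai_F(scores, group_idx), error = function(e)
    stop("singular covariance in MANOVA; try fewer components", call. = FALSE))
  if (!is.finite(res$F))
    stop("singular covariance in MANOVA; try fewer components")
  res
}

#' Null distribution of the signature MANOVA F from random gene sets
#'
#' Each draw samples `signature_size` genes uniformly without replacement
#' from the universe, restricts the expression matrix to them, recomputes the
#' leading principal components and the Pillai-trace F for group separation.
#'
#' @param expr Expression matrix (genes x samples), typically log2
#'   median-centered.
#' @param universe Character vector of gene ids eligible for resampling
#'   (annotated, expressed genes); must all be rows of `expr`.
#' @param signature_size Number of genes per random draw.
#' @param groups Factor of group labels (or [sample_design()]).
#' @param n_draws Number of random sets (default 5000).
#' @param seed Integer seed.
#' @param n_components Leading components used (default 3).
#' @param exclude Optional gene ids excluded from the universe (e.g. the
#'   real signature); by default nothing is excluded.
#' @return Numeric vector of length `n_draws` of null F statistics.
#' @export
random_geneset_null <- function(expr, universe, signature_size, groups,
                                n_draws = 5000, seed = 1L, n_components = 3,
                                exclude = NULL) {
  m <- unclass(expr)
  if (inherits(groups, "sample_design"))
    groups <- design_groups(groups, colnames(m))
  groups <- droplevels(as.factor(groups))
  if (n_draws < 1) stop("n_draws must be positive")
  universe <- setdiff(universe, exclude)
  if (!all(universe %in% rownames(m)))
    stop("universe contains genes absent from the expression matrix")
  if (length(universe) < signature_size)
    stop("universe smaller than the signature size")
  uni_idx <- match(universe, rownames(m))
  group_idx <- split(seq_len(ncol(m)), groups)
  set.seed(as.integer(seed))
  vapply(seq_len(n_draws), function(b) {
    idx <- uni_idx[sample.int(length(uni_idx), signature_size)]
    pca_manova_F_kernel(m[idx, , drop = FALSE], group_idx, n_components)$F
  }, numeric(1))
}

#' Permutation p-value from an observed statistic and null draws
#'
#' The default upper-tail rule is `p = #\{null >= observed\} / n_draws`, with
#' ties counting against the observed statistic.  `rule = "literal"` instead
#' reports `#\{null < observed\} / n_draws` (the proportion of null statistics
#' the observed value exceeds).  `add_one = TRUE` applies the
#' `(1 + k) / (1 + n)` finite-sample correction, which guarantees p > 0 and
#' is the recommended choice when the p-value feeds further inference.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null draws.
#' @param rule `"upper"` (default) or `"literal"`.
#' @param add_one Apply the add-one correction (default `FALSE`).
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(observed, null_values,
                               rule = c("upper", "literal"),
                               add_one = FALSE) {
  rule <- match.arg(rule)
  if (length(null_values) == 0) stop("empty null distribution")
  if (anyNA(null_values) || is.na(observed))
    stop("NaN/NA in permutation p-value inputs")
  k <- if (rule == "upper") sum(null_values >= observed)
       else sum(null_values < observed)
  if (add_one) (1 + k) / (1 + length(null_values))
  else k / length(null_values)
}

#' Signature-restricted PCA permutation test of group separation
#'
#' Tests whether an a-priori gene signature separates sample groups: the
#' expression matrix is restricted to the signature, the leading principal
#' components are computed (samples as observations), a one-way MANOVA
#' (Pillai's trace F) of the components on the group label gives the
#' observed statistic, and its null distribution is built from random gene
#' sets of the same size drawn from the annotated expressed-gene universe.
#'
#' @inheritParams random_geneset_null
#' @param signature Character vector of signature gene ids.
#' @param rule,add_one Passed to [permutation_pvalue()].
#' @param exclude_signature Exclude the signature's own genes from the
#'   resampling universe (default `FALSE`: nothing is excluded).
#' @return An object of class `perm_pca_result`: observed F, PC scores,
#'   variance explained, the null F vector, the p-value and provenance
#'   (seed, draw count, universe and signature sizes, p-value rule).
#' @export
signature_perm_test <- function(expr, signature, universe, groups,
                                n_draws = 5000, seed = 1L, n_components = 3,
                                rule = "upper", add_one = FALSE,
                                exclude_signature = FALSE) {
  m <- unclass(expr)
  if (inherits(groups, "sample_design"))
    groups <- design_groups(groups, colnames(m))
  groups <- droplevels(as.factor(groups))
  present <- intersect(signature, rownames(m))
  if (length(present) < 2)
    stop("fewer than 2 signature genes present in the expression matrix")
  pca <- signature_pca(m, present, n_components)
  obs <- manova_f(pca$scores, groups)
  null_f <- random_geneset_null(
    m, universe, length(present), groups, n_draws = n_draws, seed = seed,
    n_components = n_components,
    exclude = if (exclude_signature) present else NULL)
  p <- permutation_pvalue(obs$F, null_f, rule = rule, add_one = add_one)
  structure(list(observed_F = obs$F, pillai = obs$pillai,
                 pc_scores = pca$scores,
                 variance_explained = pca$variance_explained,
                 null_F = null_f, p_value = p,
                 n_draws = n_draws, seed = seed,
                 universe_size = length(setdiff(universe,
                   if (exclude_signature) present else NULL)),
                 signature_size = length(present),
                 n_signature_requested = length(signature),
                 p_rule = rule, add_one = add_one),
            class = "perm_pca_result")
}

#' @export
print.perm_pca_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Signature permutation test\n",
    "  signature genes used: %d (of %d requested), universe: %d genes\n",
    "  observed MANOVA F (Pillai) = %.4g\n",
    "  permutation p = %.4g  (%d random sets, rule = %s%s)\n"),
    x$signature_size, x$n_signature_requested, x$universe_size,
    x$observed_F, x$p_value, x$n_draws, x$p_rule,
    if (x$add_one) ", add-one corrected" else ""))
  invisible(x)
}
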