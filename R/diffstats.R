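#' Two-sided Mann-Whitney U test
#'
#' Exact p-value by the null distribution of U when both groups are at most
#' `exact_threshold` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' The two-sided exact p is the doubled smaller tail, capped at 1.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_threshold Maximum per-group size for the exact path.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counting
#'   one half), `p_value`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y, exact_threshold = 8) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= exact_threshold && n2 <= exact_threshold) {
    lower <- stats::pwilcox(u, n1, n2)
    upper <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "normal"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u, p_value = p, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with enforced monotonicity (via [stats::p.adjust()]); input
#' order is preserved.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) stop("NA/NaN p-values")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-gene Mann-Whitney differential expression with BH selection
#'
#' Runs [mann_whitney()] per gene between two groups, adjusts across genes
#' by Benjamini-Hochberg, and selects genes with q below the FDR threshold.
#' The reported effect is the log2 ratio of group medians (with a
#' pseudocount for zeros).
#'
#' @param expr Expression matrix (genes x samples), e.g. RPKM.
#' @param design A [sample_design()] (or factor aligned to the columns).
#' @param groups Length-two character vector naming the two groups compared
#'   (defaults to the first two design levels present).
#' @param fdr FDR threshold for selection (default 0.05).
#' @param pseudocount Added to medians before the log ratio.
#' @return List with `table` (gene, U, median_log2fc, p, q, selected) and
#'   `selected` (character vector of gene ids with q < fdr).
#' @export
de_genes <- function(expr, design, groups = NULL, fdr = 0.05,
                     pseudocount = 0.01) {
  m <- unclass(expr)
  g <- if (inherits(design, "sample_design"))
    design_groups(design, colnames(m)) else droplevels(as.factor(design))
  if (is.null(groups)) groups <- utils::head(levels(g), 2)
  if (length(groups) != 2 || !all(groups %in% levels(g)))
    stop("need two group labels present in the design")
  ia <- which(g == groups[1]); ib <- which(g == groups[2])
  if (length(ia) < 3 || length(ib) < 3)
    warning("fewer than 3 samples in a group; the rank test has little power")
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    mw <- mann_whitney(m[i, ia], m[i, ib])
    c(mw$U, mw$p_value)
  }, numeric(2)))
  q <- bh_adjust(res[, 2])
  lfc <- log2((apply(m[, ia, drop = FALSE], 1, stats::median) + pseudocount) /
              (apply(m[, ib, drop = FALSE], 1, stats::median) + pseudocount))
  tab <- data.frame(gene = rownames(m), U = res[, 1],
                    median_log2fc = unname(lfc),
                    p = res[, 2], q = q,
                    selected = q < fdr, stringsAsFactors = FALSE)
  list(table = tab, selected = tab$gene[tab$selected],
       groups = groups, fdr = fdr)
}

#' Per-gene 2x2 factorial test with an interaction (synergy) term
#'
#' Fits `y ~ A + B + A:B` per gene.  With `moderated = TRUE` the residual
#' variances are shrunk by the empirical-Bayes procedure of the limma
#' package (moderated t statistics); otherwise ordinary least-squares t
#' statistics are reported.  P-values are returned unadjusted: the intended
#' use is a small a-priori gene panel where each gene is tested at the
#' nominal level.
#'
#' @param expr Expression matrix (genes x samples) on a log-like scale.
#' @param factor_a,factor_b Two-level factors aligned with the columns of
#'   `expr` (or a [sample_design()] with `factor_a`/`factor_b` columns
#'   passed as `factor_a`).
#' @param moderated Use limma's empirical-Bayes moderated t (default TRUE).
#' @return data.frame per gene: effect estimates and raw p-values for the
#'   two main effects and the interaction.
#' @export
factorial_interaction_test <- function(expr, factor_a, factor_b = NULL,
                                       moderated = TRUE) {
  m <- unclass(expr)
  if (inherits(factor_a, "sample_design")) {
    d <- factor_a
    idx <- match(colnames(m), d$sample)
    if (anyNA(idx)) stop("design does not cover all samples")
    factor_b <- droplevels(factor(d$factor_b[idx]))
    factor_a <- droplevels(factor(d$factor_a[idx]))
  } else {
    factor_a <- droplevels(as.factor(factor_a))
    factor_b <- droplevels(as.factor(factor_b))
  }
  if (nlevels(factor_a) != 2 || nlevels(factor_b) != 2)
    stop("both factors must have exactly 2 levels")
  cells <- table(factor_a, factor_b)
  if (any(cells == 0)) stop("empty factorial cell")
  design <- stats::model.matrix(~ factor_a * factor_b)
  colnames(design) <- c("intercept", "A", "B", "AB")
  if (moderated) {
    fit <- limma::eBayes(limma::lmFit(m, design))
    out <- data.frame(gene = rownames(m),
                      effect_a = fit$coefficients[, "A"],
                      effect_b = fit$coefficients[, "B"],
                      interaction = fit$coefficients[, "AB"],
                      t_a = fit$t[, "A"], t_b = fit$t[, "B"],
                      t_interaction = fit$t[, "AB"],
                      p_a = fit$p.value[, "A"], p_b = fit$p.value[, "B"],
                      p_interaction = fit$p.value[, "AB"],
                      stringsAsFactors = FALSE)
  } else {
    if (any(cells < 2))
      stop("need at least 2 replicates per cell for the unmoderated test")
    n <- ncol(m)
    df <- n - ncol(design)
    xtx_inv <- solve(crossprod(design))
    beta <- m %*% design %*% xtx_inv          # genes x 4
    resid <- m - beta %*% t(design)
    s2 <- rowSums(resid^2) / df
    se <- sqrt(outer(s2, diag(xtx_inv)))
    tt <- beta / se
    pp <- 2 * stats::pt(-abs(tt), df)
    out <- data.frame(gene = rownames(m),
                      effect_a = beta[, "A"], effect_b = beta[, "B"],
                      interaction = beta[, "AB"],
                      t_a = tt[, "A"], t_b = tt[, "B"],
                      t_interaction = tt[, "AB"],
                      p_a = pp[, "A"], p_b = pp[, "B"],
                      p_interaction = pp[, "AB"],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Exact null distribution of the Jonckheere-Terpstra statistic (no ties):
# JT is distributed as the convolution of independent Mann-Whitney
# U(n_1 + ... + n_{j-1}, n_j) variables.
jt_exact_distribution <- function(group_sizes) {
  dist <- 1
  cum <- group_sizes[1]
  for (j in 2:length(group_sizes)) {
    nj <- group_sizes[j]
    dw <- stats::dwilcox(0:(cum * nj), cum, nj)
    new <- numeric(length(dist) + length(dw) - 1)
    for (u in seq_along(dw))
      new[u:(u + length(dist) - 1)] <- new[u:(u + length(dist) - 1)] +
        dw[u] * dist
    dist <- new
    cum <- cum + nj
  }
  dist  # dist[t + 1] = P(JT = t)
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests for a monotone shift across at least three ordered groups.
#' `JT` is the sum over ordered group pairs (i < j) of the number of
#' (earlier, later) observation pairs with the later value larger (ties
#' count one half).  Exact p by the null distribution when the total sample
#' size is at most `exact_threshold_total` and there are no ties; normal
#' approximation with tie-corrected variance otherwise.
#'
#' @param values Numeric vector of observations.
#' @param ordered_groups Factor whose *level order* defines the trend
#'   direction; must have at least 3 levels present.
#' @param two_sided Report the doubled smaller tail (default); otherwise the
#'   one-sided increasing-trend p.
#' @param exact_threshold_total Maximum total n for the exact path.
#' @return List with `JT`, `p_value`, `method`.
#' @export
jonckheere_terpstra <- function(values, ordered_groups, two_sided = TRUE,
                                exact_threshold_total = 12) {
  g <- as.factor(ordered_groups)
  g <- droplevels(g)
  if (nlevels(g) < 3)
    stop("need at least 3 ordered groups; use mann_whitney for 2")
  lev <- levels(g)
  split_vals <- split(values, g)
  jt <- 0
  for (i in seq_len(nlevels(g) - 1)) for (j in (i + 1):nlevels(g)) {
    xi <- split_vals[[lev[i]]]; xj <- split_vals[[lev[j]]]
    jt <- jt + sum(outer(xj, xi, ">")) + 0.5 * sum(outer(xj, xi, "=="))
  }
  sizes <- as.integer(table(g))
  n <- sum(sizes)
  ties <- anyDuplicated(values) > 0
  if (!ties && n <= exact_threshold_total) {
    dist <- jt_exact_distribution(sizes)
    upper <- sum(dist[(jt + 1):length(dist)])
    lower <- sum(dist[1:(jt + 1)])
    p <- if (two_sided) min(1, 2 * min(lower, upper)) else upper
    method <- "exact"
  } else {
    tie_tab <- table(values)
    mu <- (n^2 - sum(sizes^2)) / 4
    t1 <- n * (n - 1) * (2 * n + 5) -
      sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
      sum(tie_tab * (tie_tab - 1) * (2 * tie_tab + 5))
    t2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
      sum(tie_tab * (tie_tab - 1) * (tie_tab - 2))
    t3 <- sum(sizes * (sizes - 1)) * sum(tie_tab * (tie_tab - 1))
    sigma2 <- t1 / 72 +
      t2 / (36 * n * (n - 1) * (n - 2)) +
      t3 / (8 * n * (n - 1))
    if (sigma2 <= 0) return(list(JT = jt, p_value = 1, method = "normal"))
    z <- (jt - mu) / sqrt(sigma2)
    p <- if (two_sided) min(1, 2 * stats::pnorm(-abs(z)))
         else stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(JT = jt, p_value = p, method = method)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks for ties; exact p by the permutation distribution for
#' n <= 9 without ties (via [stats::cor.test()]), t approximation otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 4, no missing values.
#' @return List with `rho`, `p_value`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 4) stop("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- !ties && length(x) <= 9
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       method = if (exact) "exact" else "t-approximation")
}
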