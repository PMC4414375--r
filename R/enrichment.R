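#' SAM moderated difference statistic
#'
#' For each gene, `d = (mean_1 - mean_2) / (s + s0)` where `s` is the pooled
#' two-sample standard error of the mean difference and `s0` a
#' variance-stabilizing constant.  `s0 = "auto"` resolves to a percentile of
#' the per-gene standard-error distribution (default the median), a common
#' simplification of the SAM fudge factor.
#'
#' @param expr Expression matrix (genes x samples), e.g. upper-quartile
#'   normalized counts.
#' @param groups Two-level factor aligned to the columns (or a
#'   [sample_design()]); the difference is level 1 minus level 2.
#' @param s0 Non-negative number, or `"auto"`.
#' @param s0_percentile Percentile of per-gene standard errors used when
#'   `s0 = "auto"` (default 0.5).
#' @return Named numeric vector of d scores with attribute `s0` (the
#'   resolved value).
#' @export
sam_statistic <- function(expr, groups, s0 = "auto", s0_percentile = 0.5) {
  m <- unclass(expr)
  if (inherits(groups, "sample_design"))
    groups <- design_groups(groups, colnames(m))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  n1 <- length(ia); n2 <- length(ib)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(m[, ia, drop = FALSE])
  m2 <- rowMeans(m[, ib, drop = FALSE])
  ss1 <- rowSums((m[, ia, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, ib, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (identical(s0, "auto"))
    s0 <- stats::quantile(s, s0_percentile, names = FALSE)
  if (!is.numeric(s0) || s0 < 0) stop("s0 must be non-negative or 'auto'")
  d <- (m1 - m2) / (s + s0)
  names(d) <- rownames(m)
  attr(d, "s0") <- s0
  d
}

#' Rank genes by score, descending, ties broken by gene id
#'
#' @param d Named numeric score vector (no NaN).
#' @return The score vector sorted in descending order (stable, lexicographic
#'   tie-break on gene id).
#' @export
rank_genes <- function(d) {
  if (anyNA(d)) stop("NaN/NA scores")
  if (is.null(names(d))) stop("scores must be named by gene id")
  d[order(-d, names(d), method = "radix")]
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list accumulating `+1/k` at set members ("hits") and
#' `-1/(N-k)` elsewhere (unweighted, `weight_exponent = 0`); in weighted
#' mode hits contribute `|score|^exponent` normalized over the set's hits.
#' The enrichment score is the signed value of the running sum's
#' maximal-magnitude excursion.
#'
#' @param ranked Named score vector from [rank_genes()].
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent 0 (classic Kolmogorov-Smirnov form, default) or a
#'   positive exponent on the scores.
#' @return List with `es`, `running` (length-N running sum), `extremum`
#'   (index of the excursion), `hits` (logical length-N).
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 0) {
  ids <- names(ranked)
  hits <- ids %in% gene_set
  k <- sum(hits)
  if (k == 0) stop("gene set does not intersect the ranked list")
  n <- length(ranked)
  inc <- if (weight_exponent == 0) rep(1 / k, n)
         else abs(ranked)^weight_exponent /
              sum(abs(ranked[hits])^weight_exponent)
  step <- ifelse(hits, inc, if (n > k) -1 / (n - k) else 0)
  running <- cumsum(step)
  hi <- max(running); lo <- min(running)
  # ties between the positive and negative excursion resolve positive
  if (hi >= abs(lo)) {
    es <- hi; extremum <- which.max(running)
  } else {
    es <- lo; extremum <- which.min(running)
  }
  list(es = es, running = running, extremum = extremum, hits = hits)
}

# ES from sorted hit positions (1-based) among n ranked genes; weights is
# |score|^alpha over all positions (NULL for unweighted).  Mirrors gsea_es
# without materializing the full running sum.
es_from_positions <- function(pos, n, weights = NULL) {
  k <- length(pos)
  if (k == n) return(1)
  miss <- 1 / (n - k)
  if (is.null(weights)) {
    cum_hit <- seq_len(k) / k
  } else {
    w <- weights[pos]
    cum_hit <- cumsum(w) / sum(w)
  }
  after <- cum_hit - (pos - seq_len(k)) * miss
  before <- c(0, cum_hit[-k]) - (pos - seq_len(k)) * miss
  hi <- max(after)
  lo <- min(before)
  if (hi >= abs(lo)) hi else lo
}

#' Gene-label permutation null for gene-set enrichment
#'
#' Permutes the assignment of scores to gene labels (the ranking itself is
#' fixed; set membership lands on random positions) and recomputes the
#' enrichment score of every pathway per permutation.
#'
#' @param ranked Named score vector from [rank_genes()].
#' @param pathways Named list of gene-id vectors (or a
#'   [gene_set_collection()]).
#' @param n_perm Number of permutations (default 2000; fewer than 100 gives
#'   unstable p-values and a warning).
#' @param seed Integer seed.
#' @param weight_exponent Passed to the enrichment score.
#' @return Matrix of null enrichment scores, `n_perm` x pathways.
#' @export
gsea_permutation_null <- function(ranked, pathways, n_perm = 2000, seed = 1L,
                                  weight_exponent = 0) {
  if (inherits(pathways, "gene_set_collection")) pathways <- pathways$sets
  if (n_perm < 100) warning("fewer than 100 permutations: unstable p-values")
  ids <- names(ranked)
  n <- length(ids)
  idx <- lapply(pathways, function(s) {
    w <- which(ids %in% s)
    if (length(w) == 0) stop("pathway with empty intersection")
    w
  })
  weights <- if (weight_exponent == 0) NULL else abs(ranked)^weight_exponent
  null_es <- matrix(NA_real_, n_perm, length(pathways),
                    dimnames = list(NULL, names(pathways)))
  set.seed(as.integer(seed))
  invperm <- integer(n)
  for (b in seq_len(n_perm)) {
    s <- sample.int(n)
    invperm[s] <- seq_len(n)
    for (j in seq_along(idx)) {
      pos <- sort.int(invperm[idx[[j]]])
      null_es[b, j] <- es_from_positions(pos, n, weights)
    }
  }
  null_es
}

# Per-pathway normalization constants: mean |null ES| of each sign.
nes_constants <- function(null_es) {
  apply(null_es, 2, function(col) {
    pos <- mean(col[col > 0]); neg <- mean(abs(col[col < 0]))
    if (!is.finite(pos)) pos <- mean(abs(col))
    if (!is.finite(neg)) neg <- mean(abs(col))
    c(pos = pos, neg = neg)
  })
}

normalize_es <- function(es, const_pos, const_neg) {
  ifelse(es >= 0, es / const_pos, es / const_neg)
}

#' Family-wise (maxT) p-values for a pathway family
#'
#' Normalizes observed and null enrichment scores per pathway (dividing by
#' the mean `|null ES|` of matching sign), records each permutation's family
#' maximum of `|NES|`, and reports for each pathway the fraction of
#' permutations whose family maximum reaches its observed `|NES|`.
#'
#' @param observed_es Named vector of observed ES for the analyzed pathways.
#' @param null_es Null ES matrix from [gsea_permutation_null()] (columns
#'   matching `names(observed_es)`).
#' @param family Character vector of pathway names forming the family
#'   (default: all columns).
#' @return Named vector of FWER p-values for the family members.
#' @export
family_wise_p <- function(observed_es, null_es, family = colnames(null_es)) {
  if (length(family) == 0) stop("empty pathway family")
  if (!all(family %in% colnames(null_es)))
    stop("family members missing from the null matrix")
  consts <- nes_constants(null_es[, family, drop = FALSE])
  nes_obs <- vapply(family, function(p)
    normalize_es(observed_es[[p]], consts["pos", p], consts["neg", p]),
    numeric(1))
  nes_null <- sapply(family, function(p)
    normalize_es(null_es[, p], consts["pos", p], consts["neg", p]))
  fam_max <- apply(abs(nes_null), 1, max)
  p <- vapply(abs(nes_obs), function(v) mean(fam_max >= v), numeric(1))
  names(p) <- family
  p
}

#' Core enrichment (leading edge) subset
#'
#' For a positively enriched set, the set members ranked at or before the
#' running-sum maximum; for a negatively enriched ("down-regulated") set,
#' the members at or after the running-sum minimum, i.e. toward the bottom
#' of the list.
#'
#' @param ranked Named score vector from [rank_genes()].
#' @param es_result Result of [gsea_es()] for one pathway.
#' @return Character vector of core-enrichment gene ids, in ranking order.
#' @export
core_enrichment_subset <- function(ranked, es_result) {
  ids <- names(ranked)
  n <- length(ids)
  hit_pos <- which(es_result$hits)
  if (es_result$es >= 0)
    ids[hit_pos[hit_pos <= es_result$extremum]]
  else
    ids[hit_pos[hit_pos >= es_result$extremum]]
}

#' SAM-ranked gene-set enrichment analysis with gene-label permutation
#'
#' The complete enrichment stage: per-gene SAM scores between two groups,
#' descending ranking, per-pathway enrichment scores, a gene-label
#' permutation null, nominal (sign-matched) p-values, GSEA-style FDR
#' q-values by pooled normalized scores, family-wise (maxT) p-values over
#' the declared pathway family, and core-enrichment subsets.
#'
#' @param expr Expression matrix (genes x samples), typically filtered,
#'   upper-quartile-normalized counts.
#' @param groups Two-level factor or [sample_design()]; scores are group 1
#'   minus group 2, so treatment-repressed pathways have negative ES.
#' @param pathways Named list of gene-id vectors or a
#'   [gene_set_collection()].
#' @param family Pathway names over which the family-wise error is
#'   controlled (defaults to the collection's family, else all pathways).
#' @param n_perm Gene-label permutations (default 2000).
#' @param seed Integer seed.
#' @param s0,s0_percentile Passed to [sam_statistic()].
#' @param weight_exponent Passed to the enrichment score (default 0,
#'   unweighted).
#' @return An object of class `gsea_result`: `table` (per pathway: name,
#'   genes in pathway, expressed genes, ES, NES, direction, nominal p,
#'   FDR q, FWER p, core-enrichment size), `core` (named list of core gene
#'   vectors), `ranked`, `null_es`, and provenance fields.
#' @export
gsea_analysis <- function(expr, groups, pathways, family = NULL,
                          n_perm = 2000, seed = 1L,
                          s0 = "auto", s0_percentile = 0.5,
                          weight_exponent = 0) {
  collection_family <- NULL
  if (inherits(pathways, "gene_set_collection")) {
    collection_family <- pathways$family
    pathways <- pathways$sets
  }
  if (is.null(family))
    family <- if (!is.null(collection_family)) collection_family
              else names(pathways)
  d <- sam_statistic(expr, groups, s0 = s0, s0_percentile = s0_percentile)
  ranked <- rank_genes(d)
  expressed <- names(ranked)
  n_in_pathway <- lengths(pathways)
  pathways_expr <- lapply(pathways, intersect, expressed)
  if (any(lengths(pathways_expr) == 0))
    stop("pathway(s) with no expressed genes: ",
         paste(names(pathways)[lengths(pathways_expr) == 0], collapse = ", "))
  obs <- lapply(pathways_expr, function(s)
    gsea_es(ranked, s, weight_exponent = weight_exponent))
  es <- vapply(obs, `[[`, numeric(1), "es")
  null_es <- gsea_permutation_null(ranked, pathways_expr, n_perm = n_perm,
                                   seed = seed,
                                   weight_exponent = weight_exponent)
  # nominal p: sign-matched one tail over all permutations
  nominal <- vapply(seq_along(es), function(j) {
    if (es[j] >= 0) mean(null_es[, j] >= es[j])
    else mean(null_es[, j] <= es[j])
  }, numeric(1))
  consts <- nes_constants(null_es)
  nes <- vapply(seq_along(es), function(j)
    normalize_es(es[j], consts["pos", j], consts["neg", j]), numeric(1))
  nes_null <- sapply(seq_along(es), function(j)
    normalize_es(null_es[, j], consts["pos", j], consts["neg", j]))
  fdr_q <- vapply(seq_along(es), function(j) {
    if (nes[j] >= 0) {
      num_pool <- nes_null[nes_null >= 0]
      num <- if (length(num_pool)) mean(num_pool >= nes[j]) else 0
      den <- mean(nes[nes >= 0] >= nes[j])
    } else {
      num_pool <- nes_null[nes_null < 0]
      num <- if (length(num_pool)) mean(num_pool <= nes[j]) else 0
      den <- mean(nes[nes < 0] <= nes[j])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  fwer <- rep(NA_real_, length(es))
  names(fwer) <- names(pathways)
  fwer[family] <- family_wise_p(es, null_es, family)
  core <- lapply(seq_along(obs), function(j)
    core_enrichment_subset(ranked, obs[[j]]))
  names(core) <- names(pathways)
  tab <- data.frame(
    pathway = names(pathways),
    n_genes = as.integer(n_in_pathway),
    n_expressed = as.integer(lengths(pathways_expr)),
    es = unname(es), nes = unname(nes),
    direction = ifelse(es >= 0, "up", "down"),
    nominal_p = unname(nominal),
    fdr_q = unname(fdr_q),
    fwer_p = unname(fwer),
    n_core = as.integer(lengths(core)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, core = core, ranked = ranked,
                 running = lapply(obs, `[[`, "running"),
                 null_es = null_es, family = family,
                 n_permutations = n_perm, seed = as.integer(seed),
                 s0 = attr(d, "s0"), weight_exponent = weight_exponent),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "gsea_result: %d pathways, %d genes ranked, %d gene-label permutations (s0 = %.4g)\n",
    nrow(x$table), length(x$ranked), x$n_permutations, x$s0))
  print(x$table[, c("pathway", "n_genes", "n_expressed", "es",
                    "nominal_p", "fdr_q", "fwer_p")], digits = 3)
  invisible(x)
}
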