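make_two_group_expr <- function(n_genes, n_per_group = 4, seed = 1,
                                shift_genes = NULL, shift = 0) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * 2 * n_per_group, 6, 0.5), n_genes)
  if (!is.null(shift_genes)) m[shift_genes, seq_len(n_per_group)] <-
    m[shift_genes, seq_len(n_per_group)] * 2^shift
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(2 * n_per_group)))
  list(m = m, groups = factor(rep(c("treated", "vehicle"),
                                  each = n_per_group),
                              levels = c("treated", "vehicle")))
}

test_that("SAM statistic reduces to a scaled t at s0 = 0 and vanishes as s0 grows", {
  ex <- make_two_group_expr(50, seed = 71)
  d0 <- sam_statistic(ex$m, ex$groups, s0 = 0)
  for (g in c(3, 17, 42)) {
    tt <- t.test(ex$m[g, 1:4], ex$m[g, 5:8], var.equal = TRUE)$statistic
    expect_equal(unname(d0[g]), unname(tt), tolerance = 1e-9)
  }
  dinf <- sam_statistic(ex$m, ex$groups, s0 = 1e6)
  expect_true(all(abs(dinf) < 1e-2))

  flat <- matrix(rep(c(1, 2), each = 4), 1, 8,
                 dimnames = list("g1", sprintf("s%d", 1:8)))
  flat <- rbind(flat, flat + 1)
  rownames(flat) <- c("g1", "g2")
  g2 <- factor(rep(c("a", "b"), 4))
  d <- sam_statistic(flat, g2, s0 = 1)
  expect_equal(unname(d), c(0, 0), ignore_attr = TRUE)

  expect_error(sam_statistic(ex$m, factor(rep(c("a", "b", "c"),
                                              length.out = 8))), "2 groups")
})

test_that("reversing the group order negates every score and enrichment sign", {
  ex <- make_two_group_expr(60, seed = 72, shift_genes = 1:10, shift = -1)
  d1 <- sam_statistic(ex$m, ex$groups)
  d2 <- sam_statistic(ex$m, factor(ex$groups,
                                   levels = rev(levels(ex$groups))))
  expect_equal(unname(d1), -unname(d2), tolerance = 1e-12)
  set_ids <- sprintf("g%04d", 1:10)
  es1 <- gsea_es(rank_genes(d1), set_ids)$es
  es2 <- gsea_es(rank_genes(d2), set_ids)$es
  expect_equal(es1, -es2, tolerance = 1e-12)
})

test_that("gene ranking is stable, descending, with lexicographic ties", {
  d <- c(a = 3, b = 1, c = 2)
  expect_identical(names(rank_genes(d)), c("a", "c", "b"))
  tied <- c(b = 2, a = 2, c = 1)
  expect_identical(names(rank_genes(tied)), c("a", "b", "c"))
  set.seed(73)
  v <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  expect_identical(names(rank_genes(v)), names(sort(v, decreasing = TRUE)))
  expect_error(rank_genes(c(a = 1, b = NA)), "NaN|NA")
})

test_that("enrichment score attains the closed-form extremes", {
  scores <- setNames(seq(10, 0.1, length.out = 100), sprintf("g%03d", 1:100))
  ranked <- rank_genes(scores)
  top <- gsea_es(ranked, names(ranked)[1:15])
  expect_equal(top$es, 1)
  expect_equal(top$running[15], 1)
  bottom <- gsea_es(ranked, names(ranked)[86:100])
  expect_equal(bottom$es, -1)
  whole <- gsea_es(ranked, names(ranked))
  expect_equal(whole$es, 1)
  expect_error(gsea_es(ranked, c("nope1", "nope2")), "intersect")
})

test_that("running sum increments cancel over the whole list and depend on ranks only", {
  set.seed(74)
  scores <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  ranked <- rank_genes(scores)
  gene_set <- sample(names(scores), 25)
  res <- gsea_es(ranked, gene_set)
  expect_equal(tail(res$running, 1), 0, tolerance = 1e-12)
  # monotone transform of scores leaves the unweighted ES unchanged
  res2 <- gsea_es(rank_genes(tanh(scores)), gene_set)
  expect_equal(res$es, res2$es, tolerance = 1e-12)
})

test_that("core enrichment matches the brute-force leading-edge definition", {
  set.seed(75)
  for (rep in 1:20) {
    ids <- sprintf("g%03d", sample(500, 80))
    ranked <- setNames(sort(rnorm(80), decreasing = TRUE), ids)
    gene_set <- sample(ids, 12)
    res <- gsea_es(ranked, gene_set)
    expect_identical(core_enrichment_subset(ranked, res),
                     core_oracle(ids, gene_set))
  }
  # contiguous bottom block: the core is the entire set
  ranked <- setNames(80:1, sprintf("g%03d", 1:80))
  bottom <- names(ranked)[71:80]
  res <- gsea_es(ranked, bottom)
  expect_setequal(core_enrichment_subset(ranked, res), bottom)
  top <- names(ranked)[1:10]
  res_top <- gsea_es(ranked, top)
  expect_setequal(core_enrichment_subset(ranked, res_top), top)
})

test_that("gene-label permutation nulls are reproducible and degenerate correctly", {
  set.seed(76)
  scores <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  ranked <- rank_genes(scores)
  pw <- list(p1 = sample(names(scores), 20),
             p2 = sample(names(scores), 40),
             all = names(scores))
  n1 <- gsea_permutation_null(ranked, pw, n_perm = 150, seed = 5)
  n2 <- gsea_permutation_null(ranked, pw, n_perm = 150, seed = 5)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(150L, 3L))
  # whole-universe pathway: ES = 1 under every permutation
  expect_true(all(n1[, "all"] == 1))
  expect_warning(gsea_permutation_null(ranked, pw["p1"], n_perm = 50,
                                       seed = 1), "unstable")
})

test_that("family-wise maxT p-values dominate nominal p-values", {
  # hand-built 10-permutation null over 3 pathways
  null_es <- cbind(p1 = c(0.1, 0.2, -0.1, 0.3, -0.2, 0.15, -0.05, 0.25,
                          -0.3, 0.1),
                   p2 = c(0.5, -0.4, 0.2, -0.1, 0.3, -0.2, 0.4, -0.5,
                          0.1, -0.3),
                   p3 = c(0.05, 0.1, -0.05, 0.02, -0.1, 0.08, -0.02, 0.04,
                          -0.06, 0.03))
  obs <- c(p1 = 0.28, p2 = -0.45, p3 = 0.09)
  p <- family_wise_p(obs, null_es)
  # oracle: normalize by sign-matched mean |null|, count family maxima
  consts <- apply(null_es, 2, function(col)
    c(pos = mean(col[col > 0]), neg = mean(abs(col[col < 0]))))
  nes_null <- sapply(colnames(null_es), function(j)
    ifelse(null_es[, j] >= 0, null_es[, j] / consts["pos", j],
           null_es[, j] / consts["neg", j]))
  nes_obs <- ifelse(obs >= 0, obs / consts["pos", ], obs / consts["neg", ])
  fam_max <- apply(abs(nes_null), 1, max)
  oracle <- vapply(abs(nes_obs), function(v) mean(fam_max >= v), numeric(1))
  expect_equal(unname(p), unname(oracle))

  # family of one: maxT equals the sign-matched nominal p on |NES|
  p1_only <- family_wise_p(obs["p1"], null_es[, "p1", drop = FALSE], "p1")
  expect_equal(unname(p1_only), mean(abs(nes_null[, "p1"]) >= nes_obs["p1"]))
  expect_error(family_wise_p(obs, null_es, character(0)), "empty")
})

test_that("the full enrichment stage flags a planted repressed pathway", {
  ex <- make_two_group_expr(800, seed = 77, shift_genes = 1:40, shift = -1.5)
  pathways <- list(planted = sprintf("g%04d", 1:40))
  for (j in 2:8) pathways[[sprintf("rand%d", j)]] <-
    sprintf("g%04d", sample(41:800, 35))
  res <- gsea_analysis(ex$m, ex$groups, pathways, n_perm = 400, seed = 7)
  tab <- res$table
  expect_identical(tab$direction[tab$pathway == "planted"], "down")
  expect_lt(tab$fwer_p[tab$pathway == "planted"], 0.05)
  expect_true(all(tab$fwer_p >= tab$nominal_p - 1e-12))
  expect_true(all(tab$nominal_p >= 0 & tab$nominal_p <= 1))
  expect_true(all(tab$fdr_q >= 0 & tab$fdr_q <= 1))
  expect_equal(tab$n_expressed, lengths(pathways)[tab$pathway],
               ignore_attr = TRUE)
  # core genes are pathway members
  expect_true(all(res$core$planted %in% pathways$planted))
})
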