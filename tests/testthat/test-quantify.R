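test_that("RPKM matches the defining formula", {
  cm <- count_matrix(matrix(c(100, 0), 1, 2,
                            dimnames = list("g1", c("s1", "s2"))),
                     c(g1 = 1000))
  r <- compute_rpkm(cm, totals = c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(unclass(r)[1, ]), c(100, 0))

  cm <- rand_count_matrix(50, 6, seed = 10)
  r <- compute_rpkm(cm)
  tot <- colSums(cm$counts)
  for (g in seq_len(50)) for (s in seq_len(6))
    expect_equal(unclass(r)[g, s],
                 unname(cm$counts[g, s] * 1e9 /
                          (cm$gene_lengths[[g]] * tot[s])))
})

test_that("RPKM is linear in counts and rejects empty samples", {
  cm <- rand_count_matrix(20, 4, seed = 11)
  r1 <- compute_rpkm(cm)
  scaled <- cm$counts
  scaled[3, ] <- scaled[3, ] * 5
  r2 <- compute_rpkm(count_matrix(scaled, cm$gene_lengths),
                     totals = colSums(cm$counts))
  expect_equal(unclass(r2)[3, ], unclass(r1)[3, ] * 5)

  empty <- cm$counts
  empty[, 2] <- 0
  expect_error(compute_rpkm(count_matrix(empty, cm$gene_lengths)), "s02")
})

test_that("expression filter applies strict thresholds and both modes", {
  v <- rbind(
    pass      = c(rep(0.3, 8), rep(0, 2)),    # 0.8 > 0.75 -> kept
    boundary  = c(rep(0.3, 7), rep(0, 3)),    # 0.7 <= 0.75 -> dropped
    at_thresh = rep(0.2, 10),                 # not strictly > 0.2 -> dropped
    allzero   = rep(0, 10),
    low       = c(5, rep(0, 9)))
  colnames(v) <- sprintf("s%02d", 1:10)
  ex <- expr_matrix(v, "rpkm")
  kept <- filter_expressed(ex)
  expect_identical(rownames(kept), "pass")
  nz <- filter_expressed(ex, mode = "nonzero")
  expect_identical(rownames(nz), c("pass", "boundary", "at_thresh", "low"))
  # idempotent, order-stable
  expect_identical(unclass(filter_expressed(kept)), unclass(kept))
  expect_warning(filter_expressed(expr_matrix(v["allzero", , drop = FALSE],
                                              "rpkm")), "no genes")
})

test_that("minimum-count filter keeps genes by row maximum", {
  m <- rbind(a = c(9, 9, 9, 9), b = c(0, 0, 10, 0), c = c(0, 0, 0, 0))
  colnames(m) <- sprintf("s%d", 1:4)
  cm <- count_matrix(m, c(a = 1000, b = 1000, c = 1000))
  expect_identical(rownames(filter_min_counts(cm, 10)$counts), "b")
  expect_identical(filter_min_counts(cm, 0)$counts, cm$counts)

  cm <- rand_count_matrix(100, 5, seed = 12, lambda = 8)
  f <- filter_min_counts(cm, 10)
  expect_identical(rownames(f$counts),
                   rownames(cm$counts)[apply(cm$counts, 1, max) >= 10])
})

test_that("upper-quartile normalization equalizes nonzero quartiles", {
  cm <- rand_count_matrix(20, 4, seed = 13)
  uq <- upper_quartile_normalize(cm)
  q <- apply(unclass(uq), 2, function(col) quantile(col[col > 0], 0.75))
  expect_lt(diff(range(q)), 1e-9)

  # depth-scaling invariance up to the magnitude-preserving global factor:
  # rescaling samples changes the output only by one common constant
  set.seed(99)
  factors <- runif(4, 0.5, 4)
  scaled <- sweep(cm$counts, 2, factors, "*")
  uq2 <- upper_quartile_normalize(count_matrix(scaled, cm$gene_lengths))
  ratio <- unclass(uq2)[cm$counts > 0] / unclass(uq)[cm$counts > 0]
  expect_lt(diff(range(ratio)), 1e-9)
  expect_equal(unname(ratio[1]), prod(factors)^(1 / 4), tolerance = 1e-9)

  # identical columns stay identical
  same <- cbind(s1 = cm$counts[, 1], s2 = cm$counts[, 1])
  uqs <- upper_quartile_normalize(count_matrix(same, cm$gene_lengths))
  expect_equal(unclass(uqs)[, 1], unclass(uqs)[, 2], ignore_attr = TRUE)

  zero <- cm$counts
  zero[, 3] <- 0
  expect_error(upper_quartile_normalize(count_matrix(zero, cm$gene_lengths)),
               "nonzero")
})

test_that("log2 median centering matches direct recomputation", {
  cm <- rand_count_matrix(30, 7, seed = 14)
  r <- compute_rpkm(cm)
  cen <- log2_median_center(r)
  direct <- log2(unclass(r) + 0.01)
  direct <- direct - apply(direct, 1, median)
  expect_equal(unclass(cen), direct, ignore_attr = TRUE)
  # odd sample count: per-gene median exactly zero
  expect_true(all(abs(apply(unclass(cen), 1, median)) < 1e-12))
  # constant gene centers to zero
  const <- expr_matrix(matrix(2.5, 1, 5,
                              dimnames = list("g1", sprintf("s%d", 1:5))),
                       "rpkm")
  expect_true(all(unclass(log2_median_center(const)) == 0))
  # zero entries flagged as not expressed
  expect_identical(attr(cen, "not_expressed"), unclass(r) == 0)
})

test_that("count and expression tables round-trip through TSV", {
  cm <- rand_count_matrix(15, 4, seed = 15)
  cp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cm, cp, lp)
  back <- read_counts_tsv(cp, lp)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$gene_lengths, cm$gene_lengths)

  ex <- compute_rpkm(cm)
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_expr_tsv(ex, ep)
  back_ex <- read_expr_tsv(ep)
  expect_equal(unclass(back_ex), unclass(ex), ignore_attr = TRUE)
  expect_identical(attr(back_ex, "stage"), "rpkm")

  d <- sample_design(colnames(cm$counts), c("A", "A", "B", "B"),
                     levels = c("A", "B"))
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_design_tsv(d, dp)
  back_d <- read_design_tsv(dp)
  expect_identical(back_d$sample, d$sample)
  expect_identical(back_d$group, d$group)
})
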