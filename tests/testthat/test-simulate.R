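test_that("count simulation is deterministic and honours the null case", {
  cfg <- sim_config(n_genes = 300, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$counts$gene_lengths, b$counts$gene_lengths)
  expect_equal(nrow(a$counts$counts), 300)
  expect_equal(ncol(a$counts$counts), 23)  # 3 + 3 + 8 + 9
  expect_setequal(levels(a$design$group), c("CB", "NPB", "CP", "BC"))

  null_cfg <- sim_config(n_genes = 300, signature_log2fc = 0, seed = 42)
  null_sim <- simulate_counts(null_cfg)
  expect_length(null_sim$truth$signature_gene_ids, 0)
  expect_true(all(null_sim$truth$true_log2fc == 0))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_genes = 30, signature_size = 41), "exceeds")
  expect_error(sim_config(group_sizes = c(A = 1, B = 5)), "at least 2")
  expect_error(sim_config(n_genes = 100, set_size_range = c(50, 200)),
               "exceed")
})

test_that("signature genes recover the configured fold change", {
  cfg <- sim_config(n_genes = 2000, signature_log2fc = 1,
                    group_sizes = c(CP = 8, BC = 8),
                    signature_group = "BC", seed = 3)
  sim <- simulate_counts(cfg)
  rpkm <- compute_rpkm(sim$counts)
  sig <- sim$truth$signature_candidate_ids
  bc <- sim$design$sample[sim$design$group == "BC"]
  cp <- sim$design$sample[sim$design$group == "CP"]
  lfc <- log2(rowMeans(unclass(rpkm)[sig, bc]) /
                rowMeans(unclass(rpkm)[sig, cp]))
  expect_lt(abs(mean(lfc) - 1), 0.15)
})

test_that("simulated counts match the configured NB moments", {
  cfg <- sim_config(n_genes = 5000, group_sizes = c(A = 30, B = 30),
                    signature_log2fc = 0, library_size_cv = 0,
                    nb_dispersion = 0.2, seed = 9)
  sim <- simulate_counts(cfg)
  m <- sim$counts$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  big <- mu > 50   # dispersion dominates Poisson noise there
  disp_hat <- median((v[big] - mu[big]) / mu[big]^2)
  expect_lt(abs(disp_hat - 0.2), 0.08)
})

test_that("gene-set universe simulation round-trips through GMT", {
  cfg <- sim_config(n_genes = 200, signature_size = 41,
                    n_gene_sets = 5, set_size_range = c(41, 41), seed = 5)
  gs <- simulate_geneset_universe(cfg)
  expect_length(gs, 6)  # 5 random sets + planted signature
  expect_true(all(lengths(gs$sets) == 41))
  expect_identical(gs$signature, "PLANTED_SIGNATURE")

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path, signature = "PLANTED_SIGNATURE")
  expect_identical(back$sets, gs$sets)
})

test_that("random signature-sized sets from a realistic universe are unique", {
  # birthday bound: C(4617, 41) is astronomically larger than 5000^2
  set.seed(1)
  universe <- sprintf("G%04d", 1:4617)
  keys <- replicate(5000, paste(sort(sample(universe, 41)), collapse = ","))
  expect_equal(sum(duplicated(keys)), 0)
})

test_that("dormancy assay copula hits its target rank correlation", {
  com <- simulate_dormancy_assay(10, rho_true = 1, seed = 2)
  expect_equal(cor(com$expression, com$percent_g0, method = "spearman"), 1)
  expect_true(all(com$percent_g0 >= 0 & com$percent_g0 <= 100))

  indep <- simulate_dormancy_assay(1000, rho_true = 0, seed = 2)
  expect_lt(abs(cor(indep$expression, indep$percent_g0,
                    method = "spearman")), 0.1)

  pos <- vapply(1:200, function(s)
    cor(simulate_dormancy_assay(7, 0.8, seed = s)$expression,
        simulate_dormancy_assay(7, 0.8, seed = s)$percent_g0,
        method = "spearman") > 0, logical(1))
  expect_gte(mean(pos), 0.95)

  expect_error(simulate_dormancy_assay(10, rho_true = 1.2), "rho")
  expect_error(simulate_dormancy_assay(3, rho_true = 0.5), "4 samples")
})

test_that("factorial simulation is reproducible and carries its effects", {
  a <- simulate_factorial_treatment(50, c(drug_a = 1, drug_b = 0.5,
                                          interaction = 2),
                                    n_per_cell = 4, seed = 7)
  b <- simulate_factorial_treatment(50, c(drug_a = 1, drug_b = 0.5,
                                          interaction = 2),
                                    n_per_cell = 4, seed = 7)
  expect_identical(unclass(a$expr), unclass(b$expr))
  expect_equal(ncol(a$expr), 16)
  expect_equal(as.vector(table(a$design$factor_a, a$design$factor_b)),
               rep(4L, 4))
  expect_error(simulate_factorial_treatment(10, n_per_cell = 1), "at least 2")
})
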