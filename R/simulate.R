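#' Configuration for the synthetic RNA-seq cohort generator
#'
#' Defaults emulate a four-group progenitor cohort: cord blood (CB, n = 3),
#' normal peripheral blood (NPB, n = 3), chronic phase (CP, n = 8) and blast
#' crisis (BC, n = 9) samples, with an a-priori 41-gene signature elevated in
#' the BC-like group.  Counts are negative binomial with
#' `variance = mu + mu^2 * dispersion` and log-normal library sizes.
#'
#' @param n_genes Number of genes simulated.
#' @param group_sizes Named integer vector: samples per group (each >= 2).
#' @param library_size_mean Mean library size in reads.
#' @param library_size_cv Coefficient of variation of library sizes.
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param signature_size Number of genes in the planted signature.
#' @param signature_log2fc Log2 fold change applied to signature genes in
#'   `signature_group`.
#' @param signature_group Group receiving the signature effect (default the
#'   last group, the "BC-like" group).
#' @param n_gene_sets Number of random annotation sets simulated.
#' @param set_size_range Length-two integer vector: min/max set size.
#' @param length_range Range (nt) from which gene lengths are drawn.
#' @param seed Integer seed; fully determines all output.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 14000,
                       group_sizes = c(CB = 3, NPB = 3, CP = 8, BC = 9),
                       library_size_mean = 2e6,
                       library_size_cv = 0.3,
                       nb_dispersion = 0.15,
                       signature_size = 41,
                       signature_log2fc = 1,
                       signature_group = NULL,
                       n_gene_sets = 100,
                       set_size_range = c(20, 200),
                       length_range = c(500, 5000),
                       seed = 1L) {
  if (is.null(names(group_sizes)) || any(group_sizes < 2))
    stop("group_sizes must be named and each at least 2")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (signature_size > n_genes) stop("signature_size exceeds n_genes")
  if (length(set_size_range) != 2 || set_size_range[1] > set_size_range[2])
    stop("set_size_range must be (min, max)")
  if (set_size_range[2] > n_genes)
    stop("set sizes cannot exceed n_genes")
  if (is.null(signature_group))
    signature_group <- names(group_sizes)[length(group_sizes)]
  if (!signature_group %in% names(group_sizes))
    stop("signature_group is not one of the groups")
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 nb_dispersion = nb_dispersion,
                 signature_size = as.integer(signature_size),
                 signature_log2fc = signature_log2fc,
                 signature_group = signature_group,
                 n_gene_sets = as.integer(n_gene_sets),
                 set_size_range = as.integer(set_size_range),
                 length_range = length_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

gene_ids_for <- function(n) sprintf("G%06d", seq_len(n))

#' Simulate a negative-binomial count cohort with a planted signature
#'
#' Gene baseline abundances are log-normal across genes; per-sample expected
#' counts scale with a log-normal library size; signature genes have their
#' mean multiplied by `2^signature_log2fc` in the designated group only.
#' Gene lengths are uniform over `length_range` and recorded for RPKM.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]), `design`
#'   (a [sample_design()]) and `truth` (signature gene ids, per-group true
#'   log2 fold changes for signature genes, sample labels).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  gids <- gene_ids_for(n_genes)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n_samples <- length(groups)
  sids <- sprintf("S%02d_%s", seq_len(n_samples), groups)

  # log-normal abundance spread (~2 decades sd) mimics bulk RNA-seq dynamic range
  rel <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  rel <- rel / sum(rel)
  sig_idx <- sample.int(n_genes, config$signature_size)
  fc <- 2^config$signature_log2fc

  cv <- config$library_size_cv
  sdlog <- sqrt(log(1 + cv^2))
  libsize <- stats::rlnorm(n_samples,
                           meanlog = log(config$library_size_mean) - sdlog^2 / 2,
                           sdlog = sdlog)

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, n_genes, n_samples, dimnames = list(gids, sids))
  for (s in seq_len(n_samples)) {
    mu <- rel * libsize[s]
    if (groups[s] == config$signature_group && config$signature_log2fc != 0)
      mu[sig_idx] <- mu[sig_idx] * fc
    counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = size)
  }
  lengths <- stats::runif(n_genes, config$length_range[1], config$length_range[2])
  names(lengths) <- gids

  true_lfc <- matrix(0, config$signature_size, length(config$group_sizes),
                     dimnames = list(gids[sig_idx], names(config$group_sizes)))
  if (config$signature_log2fc != 0)
    true_lfc[, config$signature_group] <- config$signature_log2fc

  design <- sample_design(sids, groups, levels = names(config$group_sizes))
  truth <- list(signature_gene_ids = if (config$signature_log2fc != 0)
                  gids[sig_idx] else character(0),
                signature_candidate_ids = gids[sig_idx],
                true_log2fc = true_lfc,
                sample_labels = stats::setNames(groups, sids),
                seed = config$seed)
  list(counts = count_matrix(counts, lengths), design = design, truth = truth)
}

#' Simulate a KEGG-like gene-set universe over simulated gene identifiers
#'
#' Draws `n_gene_sets` uniform without-replacement sets over the gene
#' universe, with sizes uniform in `set_size_range`; the planted signature
#' (the designated gene ids) is added as a named set and flagged as the
#' collection's signature.  Duplicate sets are permitted but reported via a
#' message.
#'
#' @param config A [sim_config()].
#' @param signature_gene_ids Gene ids of the planted signature; when `NULL`,
#'   regenerated deterministically from `config`.
#' @return A [gene_set_collection()] whose signature set is named
#'   `"PLANTED_SIGNATURE"`.
#' @export
simulate_geneset_universe <- function(config, signature_gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_gene_sets < 1) stop("n_gene_sets must be at least 1")
  if (is.null(signature_gene_ids))
    signature_gene_ids <- simulate_counts(config)$truth$signature_candidate_ids
  gids <- gene_ids_for(config$n_genes)
  set.seed(config$seed + 1L)
  size_choices <- seq.int(config$set_size_range[1], config$set_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), config$n_gene_sets,
                                   replace = TRUE)]
  sets <- lapply(sizes, function(k) sort(sample(gids, k)))
  names(sets) <- sprintf("RANDSET_%03d", seq_along(sets))
  keys <- vapply(sets, paste, character(1), collapse = ",")
  ndup <- sum(duplicated(keys))
  if (ndup > 0)
    message(ndup, " duplicate random gene sets drawn")
  sets$PLANTED_SIGNATURE <- sort(signature_gene_ids)
  gene_set_collection(sets, signature = "PLANTED_SIGNATURE")
}

#' Simulate paired expression / percent-G0 measurements
#'
#' Emulates a dormancy assay in which per-sample transcript levels are
#' compared with the percentage of cells in G0.  Pairs are drawn from a
#' Gaussian copula whose latent Pearson correlation is chosen so the
#' population Spearman correlation equals `rho_true`
#' (`r = 2*sin(pi*rho/6)`); expression is log-normal and percent G0 is the
#' latent normal mapped through its CDF onto [0, 100].
#'
#' @param n_samples Number of pairs (>= 4).
#' @param rho_true Target Spearman correlation in [-1, 1].
#' @param seed Integer seed.
#' @return A data.frame with columns `sample`, `expression`, `percent_g0`.
#' @export
simulate_dormancy_assay <- function(n_samples, rho_true, seed = 1L) {
  if (n_samples < 4) stop("need at least 4 samples")
  if (abs(rho_true) > 1) stop("rho_true must lie in [-1, 1]")
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n_samples)
  if (abs(rho_true) == 1) {
    z2 <- sign(rho_true) * z1
  } else {
    r <- 2 * sin(pi * rho_true / 6)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_samples)
  }
  data.frame(sample = sprintf("A%02d", seq_len(n_samples)),
             expression = exp(0.5 * z1),
             percent_g0 = 100 * stats::pnorm(z2))
}

#' Simulate a 2x2 factorial treatment experiment
#'
#' Per-gene Gaussian expression with additive main effects for two drugs and
#' a configurable interaction, applied to a designated fraction of genes.
#'
#' @param n_genes Number of genes.
#' @param effects Named numeric vector with elements `drug_a`, `drug_b`,
#'   `interaction` (log2-scale shifts).
#' @param n_per_cell Replicates per factorial cell (>= 2).
#' @param noise_sd Residual standard deviation.
#' @param affected_fraction Fraction of genes carrying the effects.
#' @param seed Integer seed.
#' @return List with `expr` (an `expr_matrix`, stage `log2_centered` scale
#'   semantics are not asserted: values are modelled log-intensities),
#'   `design` (a [sample_design()] with `factor_a`, `factor_b`) and
#'   `truth$affected_gene_ids`.
#' @export
simulate_factorial_treatment <- function(n_genes,
                                         effects = c(drug_a = 0, drug_b = 0,
                                                     interaction = 0),
                                         n_per_cell = 4,
                                         noise_sd = 0.5,
                                         affected_fraction = 1,
                                         seed = 1L) {
  if (n_per_cell < 2) stop("n_per_cell must be at least 2")
  stopifnot(all(c("drug_a", "drug_b", "interaction") %in% names(effects)))
  set.seed(as.integer(seed))
  gids <- gene_ids_for(n_genes)
  a <- rep(rep(c(0, 1), each = n_per_cell), times = 2)
  b <- rep(c(0, 1), each = 2 * n_per_cell)
  n_samples <- length(a)
  sids <- sprintf("T%02d_a%d_b%d", seq_len(n_samples), a, b)
  n_aff <- round(affected_fraction * n_genes)
  affected <- sort(sample.int(n_genes, n_aff))
  base <- stats::rnorm(n_genes, mean = 6, sd = 1)
  mu <- matrix(base, n_genes, n_samples)
  eff <- matrix(0, n_genes, n_samples)
  eff[affected, ] <- outer(rep(1, n_aff),
                           effects[["drug_a"]] * a + effects[["drug_b"]] * b +
                             effects[["interaction"]] * a * b)
  values <- mu + eff + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                              n_genes, n_samples)
  dimnames(values) <- list(gids, sids)
  design <- sample_design(sids,
                          group = paste0("a", a, "b", b),
                          factor_a = a, factor_b = b)
  list(expr = expr_matrix(values, "uq_normalized"),
       design = design,
       truth = list(affected_gene_ids = gids[affected], effects = effects))
}

#' Serialize simulation ground truth as JSON
#' @param truth The `truth` element returned by [simulate_counts()].
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  tr <- truth
  tr$true_log2fc <- as.data.frame(tr$true_log2fc)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(truth)
}
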