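#' Pipeline configuration
#'
#' Collects the thresholds, permutation counts and seeds the workflows use.
#' Defaults: RPKM > 0.2 in over 75% of samples for the cohort expression
#' filter, at least 10 mapped reads in one or more samples for the
#' enrichment count filter, 5000 random signature-sized gene sets for the
#' permutation test and 2000 gene-label permutations for enrichment.
#'
#' @param min_rpkm,min_fraction Cohort expression-filter thresholds.
#' @param min_reads Enrichment count-filter threshold.
#' @param n_draws Random gene sets for the signature permutation test.
#' @param n_perm Gene-label permutations for enrichment.
#' @param n_components Leading principal components for the MANOVA.
#' @param fdr Differential-expression FDR threshold.
#' @param p_rule,add_one Permutation p-value convention
#'   (see [permutation_pvalue()]).
#' @param s0 SAM fudge constant, or `"auto"`.
#' @param weight_exponent Enrichment-score weighting (0 = unweighted).
#' @param seed Integer master seed; stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_rpkm = 0.2, min_fraction = 0.75,
                            min_reads = 10, n_draws = 5000, n_perm = 2000,
                            n_components = 3, fdr = 0.05,
                            p_rule = "upper", add_one = FALSE,
                            s0 = "auto", weight_exponent = 0, seed = 1L) {
  structure(list(min_rpkm = min_rpkm, min_fraction = min_fraction,
                 min_reads = min_reads, n_draws = n_draws, n_perm = n_perm,
                 n_components = n_components, fdr = fdr,
                 p_rule = p_rule, add_one = add_one, s0 = s0,
                 weight_exponent = weight_exponent, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration (plus input paths) from a YAML file
#'
#' Recognized top-level keys: `counts`, `lengths`, `design`, `gene_sets`
#' (paths), `signature`, `family`, `out_dir`, and any [pipeline_config()]
#' parameter.  Referenced files must exist.
#'
#' @param path YAML file.
#' @return List with `paths` (named list), `signature`, `family`, `out_dir`
#'   and `config` (a `pipeline_config`).
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  paths <- y[intersect(names(y), c("counts", "lengths", "design", "gene_sets"))]
  for (p in paths) if (!file.exists(p)) stop("input file does not exist: ", p)
  cfg_args <- y[intersect(names(y), names(formals(pipeline_config)))]
  list(paths = paths,
       signature = y$signature, family = y$family, out_dir = y$out_dir,
       config = do.call(pipeline_config, cfg_args))
}

stage_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "),
                                   sprintf(...))

#' Patient-cohort signature workflow
#'
#' Chains the cohort stages: RPKM quantification, the detectable-expression
#' filter, log2 median-centering, the signature PCA permutation test against
#' the annotated expressed-gene universe, Spearman-distance complete-linkage
#' clustering of samples and of signature genes, and Mann-Whitney/BH
#' differential expression between two designated groups.
#'
#' @param counts A [count_matrix()].
#' @param design A [sample_design()].
#' @param gene_sets A [gene_set_collection()]; its flagged signature set is
#'   tested and the union of all sets defines the annotated universe.
#' @param signature Name of the signature set (defaults to the collection's
#'   flag).
#' @param de_groups Length-two character vector of groups for differential
#'   expression (default: the last two design levels, the disease stages).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, JSON/TSV reports
#'   are written.
#' @return A report list: filtering summary, `perm_test`
#'   (a `perm_pca_result`), `sample_dendrogram`, `gene_dendrogram`, `de`
#'   and the resolved parameters.
#' @export
run_cohort_workflow <- function(counts, design, gene_sets, signature = NULL,
                                de_groups = NULL,
                                config = pipeline_config(),
                                out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(design, "sample_design"),
            inherits(gene_sets, "gene_set_collection"))
  if (is.null(signature)) signature <- gene_sets$signature
  if (is.null(signature)) stop("no signature set designated")
  log_stage("cohort: %d genes, %d samples", nrow(counts$counts),
            ncol(counts$counts))
  rpkm <- compute_rpkm(counts)
  expressed <- filter_expressed(rpkm, config$min_rpkm, config$min_fraction)
  log_stage("cohort: %d genes pass RPKM > %.2g in over %.0f%% of samples",
            nrow(expressed), config$min_rpkm, 100 * config$min_fraction)
  centered <- log2_median_center(expressed)

  annotated <- unique(unlist(gene_sets$sets))
  universe <- intersect(annotated, rownames(centered))
  sig_genes <- gene_sets$sets[[signature]]
  perm <- signature_perm_test(centered, sig_genes, universe,
                              design, n_draws = config$n_draws,
                              seed = stage_seed(config, 11L),
                              n_components = config$n_components,
                              rule = config$p_rule, add_one = config$add_one)
  log_stage("cohort: permutation p = %.4g (F = %.3g, %d draws)",
            perm$p_value, perm$observed_F, perm$n_draws)

  sig_expr <- unclass(centered)[intersect(sig_genes, rownames(centered)), ,
                                drop = FALSE]
  sample_dend <- hierarchical_cluster(spearman_distance(sig_expr, "samples"),
                                      axis = "samples")
  gene_dend <- if (nrow(sig_expr) >= 3)
    hierarchical_cluster(spearman_distance(sig_expr, "genes"), axis = "genes")
  else NULL

  if (is.null(de_groups))
    de_groups <- utils::tail(levels(design$group), 2)
  de <- de_genes(expressed, design, groups = rev(de_groups),
                 fdr = config$fdr)
  log_stage("cohort: %d DE genes at FDR < %.2g (%s vs %s)",
            length(de$selected), config$fdr, de$groups[1], de$groups[2])

  report <- list(
    n_genes_input = nrow(counts$counts),
    n_expressed = nrow(expressed),
    universe_size = perm$universe_size,
    perm_test = perm,
    sample_dendrogram = sample_dend,
    gene_dendrogram = gene_dend,
    de = de,
    parameters = config,
    signature = signature)
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  perm <- report$perm_test
  summary <- list(
    n_genes_input = report$n_genes_input,
    n_expressed = report$n_expressed,
    universe_size = report$universe_size,
    signature = report$signature,
    signature_size = perm$signature_size,
    observed_F = perm$observed_F,
    p_value = perm$p_value,
    n_draws = perm$n_draws,
    p_rule = perm$p_rule,
    add_one = perm$add_one,
    seed = perm$seed,
    n_de_genes = length(report$de$selected),
    de_groups = report$de$groups,
    parameters = unclass(report$parameters))
  jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$de$table, file.path(out_dir, "de_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(perm$pc_scores), perm$pc_scores),
    file.path(out_dir, "pc_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  dendrogram_newick(report$sample_dendrogram,
                    file.path(out_dir, "samples.nwk"))
  if (!is.null(report$gene_dendrogram))
    dendrogram_newick(report$gene_dendrogram,
                      file.path(out_dir, "genes.nwk"))
  invisible(out_dir)
}

#' Treated-vs-vehicle enrichment workflow
#'
#' Chains the enrichment stages: minimum-count filter, upper-quartile
#' normalization, SAM ranking between the two groups, GSEA with gene-label
#' permutation, FDR and family-wise (maxT) correction, and core-enrichment
#' extraction.
#'
#' @param counts A [count_matrix()].
#' @param design A [sample_design()] with exactly two groups (e.g. treated
#'   and vehicle); scores are first level minus second level.
#' @param gene_sets A [gene_set_collection()]; its `family` flag (or all
#'   sets) defines the corrected family.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for reports.
#' @return A report list with `n_genes_input`, `n_filtered`, `gsea`
#'   (a `gsea_result`) and resolved parameters.
#' @export
run_treatment_workflow <- function(counts, design, gene_sets,
                                   config = pipeline_config(),
                                   out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(design, "sample_design"),
            inherits(gene_sets, "gene_set_collection"))
  if (nlevels(droplevels(design$group)) != 2)
    stop("the treatment workflow needs exactly two groups")
  log_stage("treatment: %d genes, %d samples", nrow(counts$counts),
            ncol(counts$counts))
  filtered <- filter_min_counts(counts, config$min_reads)
  log_stage("treatment: %d genes with >= %d reads in one or more samples",
            nrow(filtered$counts), config$min_reads)
  norm <- upper_quartile_normalize(filtered)
  res <- gsea_analysis(norm, design, gene_sets,
                       n_perm = config$n_perm,
                       seed = stage_seed(config, 23L),
                       s0 = config$s0,
                       weight_exponent = config$weight_exponent)
  log_stage("treatment: smallest family-wise p = %.4g (%s)",
            min(res$table$fwer_p, na.rm = TRUE),
            res$table$pathway[which.min(res$table$fwer_p)])
  report <- list(n_genes_input = nrow(counts$counts),
                 n_filtered = nrow(filtered$counts),
                 gsea = res, parameters = config)
  if (!is.null(out_dir)) write_treatment_report(report, out_dir)
  report
}

write_treatment_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$gsea
  utils::write.table(res$table, file.path(out_dir, "gsea_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  core_df <- data.frame(
    pathway = rep(names(res$core), lengths(res$core)),
    gene = unlist(res$core, use.names = FALSE))
  utils::write.table(core_df, file.path(out_dir, "core_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_genes_input = report$n_genes_input,
    n_filtered = report$n_filtered,
    n_permutations = res$n_permutations,
    seed = res$seed,
    s0 = res$s0,
    weight_exponent = res$weight_exponent,
    family = res$family,
    parameters = unclass(report$parameters))
  jsonlite::write_json(summary, file.path(out_dir, "treatment_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
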