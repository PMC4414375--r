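#' Raw count matrix with per-gene exonic lengths
#'
#' Lightweight container for integer read counts (genes in rows, samples in
#' columns) together with the exonic length of each gene, as needed for RPKM
#' computation.  Gene and sample identifiers must be unique.
#'
#' @param counts Integer-valued matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param gene_lengths Numeric vector of exonic lengths in nucleotides, one
#'   per gene; either named by gene id or in row order.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `gene_lengths`.
#' @export
count_matrix <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing) > 0)
      stop("gene_lengths missing for: ", paste(utils::head(missing, 5), collapse = ", "))
    gene_lengths <- gene_lengths[rownames(counts)]
  } else {
    if (length(gene_lengths) != nrow(counts))
      stop("gene_lengths must match the number of genes")
    names(gene_lengths) <- rownames(counts)
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive and finite")
  structure(list(counts = counts, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Real-valued expression matrix with a processing-stage tag
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param stage One of `"rpkm"`, `"uq_normalized"`, `"log2_centered"`.
#' @return An object of class `expr_matrix`: the numeric matrix with a
#'   `stage` attribute (and, for log2-centered data, a `not_expressed`
#'   logical mask recording zero-RPKM entries for display layers).
#' @export
expr_matrix <- function(values, stage = c("rpkm", "uq_normalized", "log2_centered")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("expression values must carry gene and sample identifiers")
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (stage == "rpkm" && any(values < 0))
    stop("rpkm values must be non-negative")
  structure(values, stage = stage, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              attr(x, "stage"), nrow(x), ncol(x)))
  invisible(x)
}

expr_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) stop("not a staged expression matrix")
  s
}

stopifnot_stage <- function(x, stage) {
  if (!identical(expr_stage(x), stage))
    stop(sprintf("expected an expression matrix at stage '%s', got '%s'",
                 stage, expr_stage(x)))
}

#' Sample design table
#'
#' Maps samples to group labels, with an optional explicit ordering of group
#' levels (used by trend tests) and optional binary treatment factors for
#' 2x2 factorial designs.
#'
#' @param sample Character vector of sample identifiers.
#' @param group Group label per sample.
#' @param levels Optional ordered character vector of group levels; defaults
#'   to order of first appearance.
#' @param factor_a,factor_b Optional binary treatment indicators (coerced to
#'   factor) for factorial designs.
#' @return A `sample_design` data.frame with columns `sample`, `group` and,
#'   when given, `factor_a`, `factor_b`.
#' @export
sample_design <- function(sample, group, levels = NULL,
                          factor_a = NULL, factor_b = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("duplicate sample identifiers in design")
  if (length(group) != length(sample))
    stop("group must have one entry per sample")
  if (is.null(levels)) levels <- unique(as.character(group))
  if (!all(as.character(group) %in% levels))
    stop("group labels outside the stated levels")
  d <- data.frame(sample = sample,
                  group = factor(as.character(group), levels = levels),
                  stringsAsFactors = FALSE)
  if (!is.null(factor_a)) d$factor_a <- factor(factor_a)
  if (!is.null(factor_b)) d$factor_b <- factor(factor_b)
  class(d) <- c("sample_design", "data.frame")
  d
}

design_groups <- function(design, samples) {
  g <- design$group[match(samples, design$sample)]
  if (anyNA(g)) stop("design is missing samples: ",
                     paste(utils::head(samples[is.na(g)], 5), collapse = ", "))
  droplevels(g)
}

#' Named gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param signature Optional name of the set flagged as the a-priori
#'   signature.
#' @param family Optional character vector naming the a-priori pathway
#'   family (a subset of `names(sets)`) over which family-wise error is
#'   controlled.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, signature = NULL, family = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(signature) && !signature %in% names(sets))
    stop("signature set '", signature, "' is not in the collection")
  if (!is.null(family) && !all(family %in% names(sets)))
    stop("family names missing from the collection")
  structure(list(sets = sets, signature = signature, family = family),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets)),
              if (is.null(x$signature)) "" else
                sprintf("; signature = '%s'", x$signature)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

# ---- file formats -----------------------------------------------------------

#' Write / read counts, lengths and designs as TSV
#'
#' The on-disk layout is plain TSV: counts with a header row of sample ids
#' and gene ids in the first column; lengths as two columns
#' (`gene_id`, `length`); designs with columns `sample`, `group` and any
#' treatment factors.
#'
#' @param x Object to write.
#' @param counts_path,lengths_path,path File paths.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_counts_tsv <- function(x, counts_path, lengths_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(x$gene_lengths), length = x$gene_lengths),
    lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname tsv_io
#' @export
read_counts_tsv <- function(counts_path, lengths_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(len$length, len$gene_id))
}

#' @rdname tsv_io
#' @export
write_design_tsv <- function(x, path) {
  stopifnot(inherits(x, "sample_design"))
  df <- as.data.frame(x)
  attr(df, "levels") <- NULL
  header <- paste0("# levels: ", paste(levels(x$group), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname tsv_io
#' @export
read_design_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  lv <- NULL
  if (startsWith(first, "# levels:"))
    lv <- strsplit(sub("^# levels:\\s*", "", first), ",")[[1]]
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sample_design(df$sample, df$group, levels = lv,
                factor_a = df$factor_a, factor_b = df$factor_b)
}

#' Write an expression matrix as TSV with a stage header comment
#' @param x An `expr_matrix`.
#' @param path Output file.
#' @export
write_expr_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", expr_stage(x)), con)
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read an expression matrix written by [write_expr_tsv()]
#' @param path Input file.
#' @export
read_expr_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- if (startsWith(first, "# stage:"))
    sub("^# stage:\\s*", "", first) else "rpkm"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, stage)
}

#' Read and write gene-set collections in GMT format
#'
#' GMT is the MSigDB tab-separated layout: set name, description, then
#' member gene ids.  Reading is delegated to [fgsea::gmtPathways()].
#'
#' @param x A `gene_set_collection`.
#' @param path File path.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to the set name).
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, desc, x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(x)
}

#' @rdname write_gmt
#' @param signature,family Passed to [gene_set_collection()] when reading.
#' @export
read_gmt <- function(path, signature = NULL, family = NULL) {
  gene_set_collection(fgsea::gmtPathways(path),
                      signature = signature, family = family)
}
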