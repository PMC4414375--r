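#' Spearman correlation distance between profiles
#'
#' `d(i, j) = 1 - rho_spearman(profile_i, profile_j)`, with average ranks for
#' ties.  Profiles are the rows (`axis = "genes"`) or columns
#' (`axis = "samples"`) of an expression matrix.  Constant profiles have no
#' defined rank correlation and raise an error naming the offender.
#'
#' @param m Numeric matrix (genes x samples) or `expr_matrix`.
#' @param axis Which margin holds the profiles to compare.
#' @return A symmetric distance matrix (zero diagonal) with profile names.
#' @export
spearman_distance <- function(m, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  m <- unclass(m)
  x <- if (axis == "samples") m else t(m)   # profiles in columns
  if (nrow(x) < 3) stop("need at least 3 observations per profile")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant profile(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(x, method = "spearman")
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering (default complete linkage).  Returns
#' the merge sequence as explicit triples alongside the underlying
#' [stats::hclust()] object.
#'
#' @param dist_matrix Symmetric numeric matrix with zero diagonal, or a
#'   `dist` object.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param axis Annotation recorded in the result (`"samples"` or `"genes"`).
#' @param metric Annotation recorded in the result.
#' @return An object of class `dendrogram_result` with elements `merges`
#'   (data.frame `a`, `b`, `height`; negative entries are leaves, positive
#'   entries earlier merges, the [stats::hclust()] convention), `order`
#'   (leaf order), `labels`, `hclust`, plus the `axis`/`metric`/`linkage`
#'   tags.
#' @export
hierarchical_cluster <- function(dist_matrix, linkage = "complete",
                                 axis = "samples", metric = "spearman") {
  if (!inherits(dist_matrix, "dist")) {
    dist_matrix <- as.matrix(dist_matrix)
    if (!isSymmetric(unname(dist_matrix), tol = 1e-12))
      stop("distance matrix must be symmetric")
    if (any(abs(diag(dist_matrix)) > 1e-12))
      stop("distance matrix must have a zero diagonal")
    dist_matrix <- stats::as.dist(dist_matrix)
  }
  hc <- stats::hclust(dist_matrix, method = linkage)
  if (is.unsorted(hc$height, strictly = FALSE) && linkage == "complete")
    warning("non-monotone merge heights under complete linkage")
  structure(list(
    merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                        height = hc$height),
    order = hc$order,
    labels = hc$labels,
    hclust = hc,
    axis = axis, metric = metric, linkage = linkage),
    class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("dendrogram_result: %d leaves (%s), %s linkage on %s distance\n",
              length(x$order), x$axis, x$linkage, x$metric))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights (ultrametric tree).
#'
#' @param x A `dendrogram_result`.
#' @param path Optional file; when `NULL` the Newick string is returned.
#' @export
dendrogram_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "dendrogram_result"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}
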