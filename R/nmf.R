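#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a non-negative matrix `V ~ W %*% H` (W: genes x rank >= 0,
#' H: rank x samples >= 0) by minimizing the generalized Kullback-Leibler
#' divergence with the classic multiplicative update rules, starting from
#' random uniform factors.  The divergence uses the convention
#' `0 * log(0) = 0`; entries of `W %*% H` are floored at 1e-12 inside logs
#' and ratios.
#'
#' @param v Non-negative numeric matrix with no all-zero row or column.
#' @param rank Factorization rank, less than `min(dim(v))`.
#' @param max_iter Maximum multiplicative updates (default 2000).
#' @param tol Stop when the relative divergence change per iteration falls
#'   below this (default 1e-6).
#' @param seed Integer seed for the random initialization.
#' @return List with `w`, `h`, `divergence` (the per-iteration trace,
#'   starting from the initial factors) and `iterations`.
#' @export
nmf_brunet <- function(v, rank, max_iter = 2000, tol = 1e-6, seed = 1L) {
  v <- as.matrix(v)
  if (any(v < 0)) stop("input matrix must be non-negative")
  if (any(rowSums(v) == 0) || any(colSums(v) == 0))
    stop("input must have no all-zero row or column")
  if (rank >= min(dim(v))) stop("rank must be smaller than both dimensions")
  n <- nrow(v); p <- ncol(v)
  set.seed(as.integer(seed))
  w <- matrix(stats::runif(n * rank, max = max(v)), n, rank)
  h <- matrix(stats::runif(rank * p, max = max(v)), rank, p)

  kl_div <- function(wh) {
    wh <- pmax(wh, 1e-12)
    sum(ifelse(v > 0, v * log(v / wh), 0) - v + wh)
  }
  wh <- w %*% h
  trace <- numeric(max_iter + 1)
  trace[1] <- kl_div(wh)
  it <- 0
  for (it in seq_len(max_iter)) {
    # H update
    ratio <- v / pmax(wh, 1e-12)
    h <- h * (crossprod(w, ratio) / colSums(w))
    wh <- w %*% h
    # W update
    ratio <- v / pmax(wh, 1e-12)
    w <- w * (ratio %*% t(h)) / rep(rowSums(h), each = n)
    wh <- w %*% h
    trace[it + 1] <- kl_div(wh)
    rel <- abs(trace[it] - trace[it + 1]) / max(abs(trace[it]), 1e-12)
    if (rel < tol) break
  }
  dimnames(w) <- list(rownames(v), paste0("factor", seq_len(rank)))
  dimnames(h) <- list(paste0("factor", seq_len(rank)), colnames(v))
  list(w = w, h = h, divergence = trace[seq_len(it + 1)], iterations = it)
}

# arg-max factor per sample column of H; ties -> lowest factor index
nmf_assign <- function(h) apply(h, 2, which.max)

#' Consensus matrix over random NMF restarts
#'
#' Runs [nmf_brunet()] `n_runs` times from different random initializations,
#' assigns each sample to its arg-max row of `H` per run, and averages the
#' resulting connectivity matrices.  `C(i, j)` is the fraction of runs in
#' which samples i and j were assigned to the same factor.
#'
#' @inheritParams nmf_brunet
#' @param n_runs Number of random restarts (default 200).
#' @return An object of class `nmf_consensus_result`: `rank`, `consensus`
#'   (samples x samples, symmetric, unit diagonal), `cophenetic_rho`,
#'   `assignments` (runs x samples), `n_runs`, `seed`.
#' @export
consensus_matrix <- function(v, rank, n_runs = 200, seed = 1L,
                             max_iter = 2000, tol = 1e-6) {
  v <- as.matrix(v)
  p <- ncol(v)
  consensus <- matrix(0, p, p, dimnames = list(colnames(v), colnames(v)))
  assignments <- matrix(NA_integer_, n_runs, p)
  for (r in seq_len(n_runs)) {
    fit <- nmf_brunet(v, rank, max_iter = max_iter, tol = tol,
                      seed = as.integer(seed) + r - 1L)
    a <- nmf_assign(fit$h)
    assignments[r, ] <- a
    consensus <- consensus + outer(a, a, "==")
  }
  consensus <- consensus / n_runs
  rho <- tryCatch(cophenetic_coefficient(consensus),
                  error = function(e) NA_real_)
  structure(list(rank = rank, consensus = consensus,
                 cophenetic_rho = rho,
                 assignments = assignments,
                 n_runs = n_runs, seed = as.integer(seed)),
            class = "nmf_consensus_result")
}

#' @export
print.nmf_consensus_result <- function(x, ...) {
  cat(sprintf(
    "nmf_consensus_result: rank %d, %d runs, cophenetic rho = %.4f\n",
    x$rank, x$n_runs, x$cophenetic_rho))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Pearson correlation between the consensus distances `1 - C` and the
#' cophenetic distances of the average-linkage dendrogram built on them.
#' Values near 1 indicate stable, block-like consensus.
#'
#' @param consensus Consensus matrix (symmetric, unit diagonal) or an
#'   `nmf_consensus_result`.
#' @return The cophenetic correlation coefficient.
#' @export
cophenetic_coefficient <- function(consensus) {
  if (inherits(consensus, "nmf_consensus_result"))
    consensus <- consensus$consensus
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0)
    stop("constant consensus matrix: cophenetic coefficient undefined")
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(coph) == 0)
    stop("degenerate dendrogram: cophenetic coefficient undefined")
  stats::cor(as.vector(d), as.vector(coph))
}

#' Factorization rank survey with a randomized baseline
#'
#' For each candidate rank, computes the consensus cophenetic coefficient on
#' the data (`n_runs` restarts) and on a randomized dataset in which each
#' gene row is independently permuted (`n_runs_randomized` restarts),
#' destroying between-sample structure while preserving per-gene marginals.
#'
#' @inheritParams consensus_matrix
#' @param ranks Integer vector of ranks to survey.
#' @param n_runs Restarts per rank on the data (default 50).
#' @param n_runs_randomized Restarts per rank on the randomized data
#'   (default 25).
#' @return data.frame with columns `rank`, `cophenetic_rho`,
#'   `cophenetic_rho_randomized`.
#' @export
rank_survey <- function(v, ranks, n_runs = 50, n_runs_randomized = 25,
                        seed = 1L, max_iter = 2000, tol = 1e-6) {
  v <- as.matrix(v)
  set.seed(as.integer(seed))
  v_rand <- t(apply(v, 1, sample))
  dimnames(v_rand) <- dimnames(v)
  out <- lapply(seq_along(ranks), function(i) {
    k <- ranks[i]
    real <- consensus_matrix(v, k, n_runs = n_runs,
                             seed = as.integer(seed) + 1000L * i,
                             max_iter = max_iter, tol = tol)
    rand <- consensus_matrix(v_rand, k, n_runs = n_runs_randomized,
                             seed = as.integer(seed) + 1000L * i + 500L,
                             max_iter = max_iter, tol = tol)
    data.frame(rank = k,
               cophenetic_rho = real$cophenetic_rho,
               cophenetic_rho_randomized = rand$cophenetic_rho)
  })
  do.call(rbind, out)
}

#' Select a factorization rank from a survey
#'
#' Applies the classic consensus-clustering rule: walk the cophenetic curve
#' in increasing rank order and pick the rank at which it stops rising,
#' i.e. the last rank of the initial non-decreasing run (the point where
#' the cophenetic coefficient begins to fall).
#'
#' @param survey A data.frame from [rank_survey()] (ranks in increasing
#'   order).
#' @return The selected rank.
#' @export
select_rank <- function(survey) {
  rho <- survey$cophenetic_rho
  if (anyNA(rho)) stop("survey contains undefined cophenetic coefficients")
  j <- 1
  while (j < length(rho) && rho[j + 1] >= rho[j]) j <- j + 1
  survey$rank[j]
}
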