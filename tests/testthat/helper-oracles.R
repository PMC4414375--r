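# Shared fixtures and independent brute-force oracles.

rand_count_matrix <- function(n_genes, n_samples, seed = 1,
                              lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m, setNames(runif(n_genes, 500, 5000), rownames(m)))
}

# Three planted sample blocks with multiplicative log-normal noise, for
# consensus-NMF rank recovery.
planted_blocks <- function(seed, n_per_block_samples = 6,
                           n_per_block_genes = 8, hi = 8, sdlog = 0.8) {
  set.seed(seed)
  ng <- 3 * n_per_block_genes
  ns <- 3 * n_per_block_samples
  mu <- matrix(1, ng, ns)
  for (b in 1:3)
    mu[(b - 1) * n_per_block_genes + seq_len(n_per_block_genes),
       (b - 1) * n_per_block_samples + seq_len(n_per_block_samples)] <- hi
  v <- mu * matrix(rlnorm(ng * ns, sdlog = sdlog), ng)
  dimnames(v) <- list(sprintf("g%02d", seq_len(ng)),
                      sprintf("s%02d", seq_len(ns)))
  v
}

# --- enumeration oracles -----------------------------------------------------

# Mann-Whitney U for a label assignment (x indices within the pooled vector).
mw_u_of <- function(pool, idx_x) {
  r <- rank(pool)
  sum(r[idx_x]) - length(idx_x) * (length(idx_x) + 1) / 2
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments;
# doubled smaller tail, capped at 1.
mw_exact_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  obs <- mw_u_of(pool, seq_len(n1))
  combs <- combn(length(pool), n1)
  us <- apply(combs, 2, function(idx) mw_u_of(pool, idx))
  lower <- mean(us <= obs)
  upper <- mean(us >= obs)
  min(1, 2 * min(lower, upper))
}

jt_statistic_of <- function(values, labels, n_levels) {
  jt <- 0
  for (i in seq_len(n_levels - 1)) for (j in (i + 1):n_levels) {
    xi <- values[labels == i]; xj <- values[labels == j]
    jt <- jt + sum(outer(xj, xi, ">")) + 0.5 * sum(outer(xj, xi, "=="))
  }
  jt
}

# All assignments of n items into groups of the given sizes (label vectors).
all_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(remaining, labels, level) {
    if (level > length(sizes)) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (idx in asplit(combn(remaining, sizes[level]), 2)) {
      labels2 <- labels
      labels2[idx] <- level
      recurse(setdiff(remaining, idx), labels2, level + 1)
    }
  }
  recurse(seq_len(n), integer(n), 1)
  out
}

# Exact Jonckheere-Terpstra p by full enumeration of label assignments.
jt_exact_oracle <- function(values, labels, two_sided = TRUE) {
  sizes <- as.integer(table(labels))
  obs <- jt_statistic_of(values, as.integer(labels), length(sizes))
  stats <- vapply(all_assignments(sizes), function(lab)
    jt_statistic_of(values, lab, length(sizes)), numeric(1))
  lower <- mean(stats <= obs)
  upper <- mean(stats >= obs)
  if (two_sided) min(1, 2 * min(lower, upper)) else upper
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Exact two-sided Spearman p: P(|rho_perm| >= |rho_obs|) over all n!
# permutations (equals the doubled smaller tail by symmetry).
spearman_exact_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- all_perms(length(x))
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Brute-force O(n^3) agglomerative clustering with complete linkage.
# Returns merges as a list of (height, members-of-new-cluster), and the
# sequence of merged member sets for comparison.
complete_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    merges[[length(merges) + 1]] <- list(height = best[1], members = merged)
    clusters[[i]] <- merged
    clusters[[j]] <- NULL
  }
  merges
}

# Merge member-sets from a dendrogram_result (hclust merge convention).
dendrogram_member_sets <- function(dend) {
  merge <- as.matrix(dend$merges[, c("a", "b")])
  sets <- vector("list", nrow(merge))
  members <- function(id) if (id < 0) -id else sets[[id]]
  for (k in seq_len(nrow(merge))) {
    sets[[k]] <- sort(unname(c(members(merge[k, 1]), members(merge[k, 2]))))
  }
  sets
}

# Direct running-sum GSEA oracle (unweighted).
gsea_running_oracle <- function(ranked_ids, gene_set) {
  n <- length(ranked_ids)
  hit <- ranked_ids %in% gene_set
  k <- sum(hit)
  step <- ifelse(hit, 1 / k, -1 / (n - k))
  running <- cumsum(step)
  hi <- max(running); lo <- min(running)
  es <- if (hi >= abs(lo)) hi else lo
  list(es = es, running = running)
}

# Core-enrichment oracle applied to the running-sum definition.
core_oracle <- function(ranked_ids, gene_set) {
  o <- gsea_running_oracle(ranked_ids, gene_set)
  hit_pos <- which(ranked_ids %in% gene_set)
  if (o$es >= 0) {
    ext <- which.max(o$running)
    ranked_ids[hit_pos[hit_pos <= ext]]
  } else {
    ext <- which.min(o$running)
    ranked_ids[hit_pos[hit_pos >= ext]]
  }
}
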