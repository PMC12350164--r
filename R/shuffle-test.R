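# fast internal PC1: gene-standardized matrix -> coherence + scores
pc1_stats <- function(xs, trim = 0.02) {
  cv <- crossprod(xs) / (nrow(xs) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  scores <- drop(xs %*% eg$vectors[, 1])
  coherence <- eg$values[1] / sum(pmax(eg$values, 0))
  list(coherence = coherence, gap = gap_statistic(scores, trim),
       scores = scores)
}

# largest spacing of the sorted scores over the central (1 - 2*trim)
# portion, standardized by the score sd. The tails are trimmed because
# the edges of a bounded gradient are sparsely populated, so extreme
# spacings there say nothing about interior discreteness.
gap_statistic <- function(scores, trim = 0.02) {
  s <- sort(scores)
  n <- length(s)
  lo <- max(1, floor(n * trim))
  hi <- min(n, ceiling(n * (1 - trim)))
  max(diff(s[lo:hi])) / sd(scores)
}

standardize_genes <- function(normed) {
  sds <- apply(normed, 2, sd)
  keep <- sds > 0
  scale(normed[, keep, drop = FALSE])
}

#' Continuity-versus-discreteness shuffle test for an expression gradient
#'
#' Tests whether within-cell-type transcriptomic heterogeneity forms a
#' continuous gradient or discrete subtypes by shuffling gene
#' expression in two ways and recomputing PC1 after each permutation:
#'
#' * Scheme A permutes each gene's values independently across all
#'   cells, destroying coordinated expression. The *coherence*
#'   statistic (PC1 variance-explained fraction) of the observed data
#'   is compared against this null:
#'   `p_coherence = Pr(null_A coherence >= observed)`.
#'   A small value means the gradient reflects
#'   coordinated gene expression rather than independent per-gene
#'   noise.
#' * Scheme B permutes each gene only within artificial clusters —
#'   `n_clusters` equal-frequency bins along the observed PC1, an
#'   arbitrary partition that deliberately ignores any real cluster
#'   structure. Within-bin shuffling collapses a continuous gradient
#'   into separated blobs (manufacturing gaps), whereas for genuinely
#'   discrete data a bin straddling the true gap produces chimeric
#'   cells that fill it. The *gap* statistic (largest spacing of the
#'   sorted PC1 scores over their central portion, standardized by
#'   the score sd) is compared: `p_gap = Pr(null_B gap <= observed)`.
#'   Continuous data give a small `p_gap`; discrete data a large one.
#'
#' @param normed normalized (cells x genes) matrix restricted to the
#'   genes of interest.
#' @param n_clusters number of artificial clusters (equal-frequency
#'   bins along PC1); 3 by default so that a two-cluster structure
#'   cannot align with the bin boundaries.
#' @param n_perm number of permutations per scheme (>= 100 advised).
#' @param trim tail fraction excluded on each side when locating the
#'   gap.
#' @param seed integer RNG seed.
#' @return list of class `ShuffleTestResult`: `observed` (coherence,
#'   gap), `null_all` and `null_within` (data frames of both
#'   statistics, `n_perm` rows each), `p_coherence`, `p_gap`,
#'   `clusters`, `n_perm`, `seed`.
#' @export
continuity_shuffle_test <- function(normed, n_clusters = 3, n_perm = 1000,
                                    trim = 0.02, seed = 1L) {
  stopifnot(n_clusters >= 2, nrow(normed) >= 2 * n_clusters)
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  set.seed(seed)
  xs <- standardize_genes(normed)
  obs <- pc1_stats(xs, trim)
  cl <- cut(rank(obs$scores, ties.method = "first"), n_clusters,
            labels = FALSE)
  n <- nrow(xs)
  g <- ncol(xs)
  idx_by_cl <- split(seq_len(n), cl)

  null_all <- matrix(NA_real_, n_perm, 2)
  null_within <- matrix(NA_real_, n_perm, 2)
  for (p in seq_len(n_perm)) {
    # scheme A: independent permutation of each gene across all cells
    xa <- xs
    for (j in seq_len(g)) xa[, j] <- xs[sample.int(n), j]
    sa <- pc1_stats(xa, trim)
    null_all[p, ] <- c(sa$coherence, sa$gap)
    # scheme B: independent permutation of each gene within clusters
    xb <- xs
    for (ii in idx_by_cl) {
      for (j in seq_len(g)) xb[ii, j] <- xs[ii[sample.int(length(ii))], j]
    }
    sb <- pc1_stats(xb, trim)
    null_within[p, ] <- c(sb$coherence, sb$gap)
  }
  p_coherence <- (1 + sum(null_all[, 1] >= obs$coherence)) / (n_perm + 1)
  p_gap <- (1 + sum(null_within[, 2] <= obs$gap)) / (n_perm + 1)
  structure(list(
    observed = list(coherence = obs$coherence, gap = obs$gap),
    null_all = data.frame(coherence = null_all[, 1], gap = null_all[, 2]),
    null_within = data.frame(coherence = null_within[, 1],
                             gap = null_within[, 2]),
    p_coherence = p_coherence, p_gap = p_gap, clusters = cl,
    n_perm = n_perm, seed = seed), class = "ShuffleTestResult")
}

#' Per-group Spearman correlation with bootstrap confidence intervals
#'
#' Rank correlation between two per-cell measurements (e.g. normalized
#' expression of a gene pair) computed separately within each group
#' (brain for FISH counts, genotype for scRNA-seq), so the two assays
#' are compared on the same footing. The CI is a seeded bootstrap
#' percentile interval over cells within the group.
#'
#' @param values_a,values_b numeric vectors (same length).
#' @param groups group label per observation.
#' @param n_boot bootstrap resamples per group.
#' @param seed integer RNG seed.
#' @param min_n minimum group size (smaller groups are dropped).
#' @return data frame with columns `group`, `r_s`, `n`, `ci_lo`,
#'   `ci_hi`; `r_s` is `NA` when either vector is constant within the
#'   group.
#' @export
pair_correlation <- function(values_a, values_b, groups = rep("all", length(values_a)),
                             n_boot = 1000, seed = 1L, min_n = 3) {
  stopifnot(length(values_a) == length(values_b),
            length(groups) == length(values_a))
  set.seed(seed)
  out <- lapply(unique(groups), function(gr) {
    sel <- groups == gr
    a <- values_a[sel]; b <- values_b[sel]
    n <- length(a)
    if (n < min_n) return(NULL)
    if (sd(a) == 0 || sd(b) == 0)
      return(data.frame(group = gr, r_s = NA_real_, n = n,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    rs <- cor(a, b, method = "spearman")
    boots <- vapply(seq_len(n_boot), function(i) {
      ii <- sample.int(n, replace = TRUE)
      suppressWarnings(cor(a[ii], b[ii], method = "spearman"))
    }, numeric(1))
    ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(group = gr, r_s = rs, n = n, ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, out)
}
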