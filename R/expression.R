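#' Quality-control filter on per-cell transcript totals
#'
#' Retains cells with `min_total <= total transcripts <= max_total`
#' and, when a mitochondrial gene list is supplied, a mitochondrial
#' fraction at most `max_mito_frac`. Cells with fewer than `min_total`
#' or more than `max_total` transcripts are removed (the bounds
#' themselves are kept).
#'
#' @param counts cells x genes non-negative integer matrix.
#' @param cell_meta optional per-cell metadata data frame (same row
#'   order), filtered alongside.
#' @param min_total,max_total inclusive bounds on per-cell totals.
#' @param max_mito_frac maximum mitochondrial transcript fraction.
#' @param mito_genes character vector of mitochondrial gene names
#'   (empty = skip that rule).
#' @return list with filtered `counts` and `cell_meta`.
#' @export
qc_filter <- function(counts, cell_meta = NULL, min_total = 10000,
                      max_total = 50000, max_mito_frac = 0.10,
                      mito_genes = character(0)) {
  totals <- rowSums(counts)
  keep <- totals >= min_total & totals <= max_total
  mito_genes <- intersect(mito_genes, colnames(counts))
  if (length(mito_genes) > 0) {
    mito_frac <- rowSums(counts[, mito_genes, drop = FALSE]) / pmax(totals, 1)
    keep <- keep & mito_frac <= max_mito_frac
  }
  if (!any(keep)) stop("QC filter removed all cells", call. = FALSE)
  list(counts = counts[keep, , drop = FALSE],
       cell_meta = if (is.null(cell_meta)) NULL
                   else cell_meta[keep, , drop = FALSE])
}

#' Log-normalize counts to transcripts per 10,000 (TP10K)
#'
#' Each cell's counts are scaled to a total of 10^4 and transformed as
#' `log(1 + 10^4 * count / total)`.
#'
#' @param counts cells x genes count matrix with positive row totals.
#' @return matrix of the same shape.
#' @export
normalize_log <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("zero-total cell encountered; run qc_filter first", call. = FALSE)
  log1p(1e4 * counts / totals)
}

#' Select highly variable genes
#'
#' Genes are ranked by the variance of their normalized values after
#' standardization within equal-frequency mean-expression bins (which
#' removes the mean-variance trend), and the top `n_hvg` are returned.
#' Ties are broken lexicographically by gene name for determinism.
#'
#' @param normed normalized matrix from [normalize_log()].
#' @param n_hvg number of genes to keep (capped at the gene count).
#' @param n_bins number of equal-frequency mean bins.
#' @return character vector of selected gene names.
#' @export
select_hvg <- function(normed, n_hvg = 500, n_bins = 20) {
  mu <- colMeans(normed)
  v <- apply(normed, 2, var)
  # keep >= 10 genes per bin so the within-bin standardization is stable
  n_bins <- max(1L, min(n_bins, length(unique(mu)), ncol(normed) %/% 10L))
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  score <- numeric(length(v))
  for (b in unique(bins)) {
    sel <- bins == b
    mb <- mean(v[sel])
    sb <- sd(v[sel])
    score[sel] <- if (is.na(sb) || sb == 0) 0 else (v[sel] - mb) / sb
  }
  genes <- colnames(normed)
  ord <- order(-score, genes)
  genes[ord][seq_len(min(n_hvg, length(genes)))]
}

#' Principal-component gradient of a normalized expression matrix
#'
#' PCA of the gene-standardized matrix. The PC1 sign is fixed so that
#' the top-|loading| gene has a positive loading, making scores
#' comparable across runs; the same convention is applied to every
#' returned PC.
#'
#' @param normed normalized (cells x genes) matrix, typically already
#'   restricted to highly variable genes.
#' @param k number of PCs to return (the fit may return fewer for
#'   rank-deficient input, with a message).
#' @return list of class `GradientResult` with `pc_scores` (cells x
#'   k, zero mean per PC), `loadings` (genes x k),
#'   `variance_explained` (fraction per PC, non-increasing) and `hvg`
#'   (the gene names used).
#' @export
pca_gradient <- function(normed, k = 5) {
  stopifnot(nrow(normed) >= k + 1)
  sds <- apply(normed, 2, sd)
  keep <- sds > 0
  x <- scale(normed[, keep, drop = FALSE])
  fit <- prcomp(x, center = FALSE, scale. = FALSE)
  k_eff <- min(k, ncol(fit$rotation))
  if (k_eff < k) message("rank-deficient input: returning ", k_eff, " PCs")
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- fit$x[, seq_len(k_eff), drop = FALSE]
  load <- fit$rotation[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(pc_scores = scores, loadings = load,
                 variance_explained = ve[seq_len(k_eff)],
                 hvg = colnames(normed)[keep]),
            class = "GradientResult")
}

#' Association of PC1 with biological and technical covariates
#'
#' Continuous covariates are tested by Spearman rank correlation with
#' the PC1 scores; categorical covariates by a Kruskal-Wallis
#' rank-based one-way test across levels. P-values are reported raw
#' (no multiple-testing correction), as the checks are diagnostic.
#'
#' @param gradient a [pca_gradient()] result.
#' @param cell_meta data frame of per-cell covariates (rows aligned
#'   with the score rows); non-numeric columns are treated as
#'   categorical.
#' @return data frame with columns `covariate`, `type`, `statistic`,
#'   `p` (`NA` for constant covariates).
#' @export
covariate_association <- function(gradient, cell_meta) {
  stopifnot(inherits(gradient, "GradientResult"))
  pc1 <- gradient$pc_scores[, 1]
  stopifnot(nrow(cell_meta) == length(pc1))
  res <- lapply(names(cell_meta), function(nm) {
    v <- cell_meta[[nm]]
    if (length(unique(v)) < 2)
      return(data.frame(covariate = nm, type = "constant",
                        statistic = NA_real_, p = NA_real_))
    if (is.numeric(v)) {
      ct <- suppressWarnings(cor.test(pc1, v, method = "spearman"))
      data.frame(covariate = nm, type = "continuous",
                 statistic = unname(ct$estimate), p = ct$p.value)
    } else {
      kt <- kruskal.test(pc1, factor(v))
      data.frame(covariate = nm, type = "categorical",
                 statistic = unname(kt$statistic), p = kt$p.value)
    }
  })
  do.call(rbind, res)
}
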