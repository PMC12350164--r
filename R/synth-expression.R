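#' Specification for a synthetic graded neuronal population
#'
#' Describes a cell population whose gene expression varies along a
#' latent dorsoventral axis in `[0, 1]`. Counts are negative-binomial
#' with mean `coverage_multiplier * baseline_mean * exp(gradient_coef *
#' (position - 0.5))` and variance `mu + mu^2 / dispersion`. With
#' `n_clusters = 0` the latent positions are continuous (uniform);
#' with `n_clusters = k >= 2` positions take exactly k equispaced
#' values, emulating discrete subtypes.
#'
#' @param n_cells number of cells (>= 2).
#' @param genes data frame with columns `name`, `baseline_mean`
#'   (expected counts/cell at the axis midpoint under unit coverage),
#'   `gradient_coef` (log-fold change per unit latent position) and
#'   `dispersion` (NB overdispersion, > 0).
#' @param n_clusters 0 for a continuous gradient, k >= 2 for discrete
#'   subtypes at equispaced latent positions.
#' @param n_replicates number of replicate (genotype) labels.
#' @param coverage_sdlog log-sd of the per-cell lognormal coverage
#'   multiplier (median 1).
#' @param seed integer RNG seed.
#' @return An object of class `GradientPopulationSpec`.
#' @export
gradient_population_spec <- function(n_cells = 600,
                                     genes = default_gradient_genes(),
                                     n_clusters = 0,
                                     n_replicates = 6,
                                     coverage_sdlog = 0.3,
                                     seed = 1L) {
  stopifnot(n_cells >= 2, is.data.frame(genes),
            all(c("name", "baseline_mean", "gradient_coef", "dispersion") %in%
                  names(genes)))
  if (any(genes$dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  if (any(!is.finite(genes$baseline_mean)) || any(genes$baseline_mean < 0) ||
      any(!is.finite(genes$gradient_coef)))
    stop("non-finite or negative gene parameters", call. = FALSE)
  if (!(n_clusters == 0 || n_clusters >= 2))
    stop("n_clusters must be 0 or >= 2", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), genes = genes,
                 n_clusters = as.integer(n_clusters),
                 n_replicates = as.integer(n_replicates),
                 coverage_sdlog = coverage_sdlog, seed = as.integer(seed)),
            class = "GradientPopulationSpec")
}

#' Default gene panel for the synthetic gradient population
#'
#' Thirty genes, half with positive and half with negative dorsoventral
#' log-fold coefficients, mirroring a panel of top gradient genes
#' (recognition-molecule transcripts running antiparallel along the
#' axis, e.g. a dpr13-like dorsal-high gene versus a SiaT-like
#' ventral-high gene).
#'
#' @param n_genes number of genes (even).
#' @param coef absolute log-fold change per unit latent position.
#' @param baseline_mean expected counts/cell at the axis midpoint.
#' @param dispersion NB overdispersion.
#' @return data frame usable as the `genes` field of
#'   [gradient_population_spec()].
#' @export
default_gradient_genes <- function(n_genes = 30, coef = 2,
                                   baseline_mean = 20, dispersion = 5) {
  stopifnot(n_genes >= 2, n_genes %% 2 == 0)
  data.frame(
    name = sprintf("g%02d", seq_len(n_genes)),
    baseline_mean = baseline_mean,
    gradient_coef = rep(c(coef, -coef), each = n_genes / 2),
    dispersion = dispersion,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cell-by-gene count matrix with known gradient
#'
#' Draws negative-binomial counts for every (cell, gene) pair with mean
#' `coverage_multiplier * baseline_mean * exp(gradient_coef *
#' (position - 0.5))`, populates per-cell metadata (replicate, sex, age
#' group, coverage = realized row totals) and returns the true latent
#' positions alongside. Identical spec (including seed) gives
#' identical output.
#'
#' @param spec a [gradient_population_spec()].
#' @return list with elements `counts` (cells x genes integer matrix),
#'   `cell_meta` (data frame: cell_id, replicate, sex, age_group,
#'   coverage), `genes` and `truth` (data frame: cell_id, latent
#'   position, cluster when discrete).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "GradientPopulationSpec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  g <- spec$genes
  if (spec$n_clusters == 0) {
    pos <- runif(n)
    cluster <- rep(NA_integer_, n)
  } else {
    k <- spec$n_clusters
    centres <- seq(0, 1, length.out = k)
    cluster <- sample.int(k, n, replace = TRUE)
    pos <- centres[cluster]
  }
  covmult <- exp(rnorm(n, 0, spec$coverage_sdlog))
  mu <- outer(covmult, g$baseline_mean) *
    exp(outer(pos - 0.5, g$gradient_coef))
  if (any(!is.finite(mu))) stop("non-finite NB means; reject spec", call. = FALSE)
  counts <- matrix(
    rnbinom(n * nrow(g), mu = as.numeric(mu),
            size = rep(g$dispersion, each = n)),
    nrow = n, dimnames = list(sprintf("cell_%04d", seq_len(n)), g$name))
  meta <- data.frame(
    cell_id = rownames(counts),
    replicate = sprintf("rep%d", sample.int(spec$n_replicates, n, replace = TRUE)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_group = sample(c("early", "late"), n, replace = TRUE),
    coverage = rowSums(counts),
    stringsAsFactors = FALSE)
  truth <- data.frame(cell_id = rownames(counts), position = pos,
                      cluster = cluster, stringsAsFactors = FALSE)
  list(counts = counts, cell_meta = meta, genes = g, truth = truth)
}
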