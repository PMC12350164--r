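#' Specification for a synthetic HCR-FISH image volume
#'
#' Describes an imaging volume containing blurred nuclei plus
#' point-like FISH puncta whose per-nucleus rates follow a linear
#' dorsoventral gradient along the volume's y axis (larger y = more
#' dorsal). The generator reproduces the acquisition artefacts a
#' volumetric pipeline must tolerate: per-channel contrast variation,
#' background noise fluctuation, and localized brightness variation
#' across nuclei.
#'
#' @param shape integer length-3 `(z, y, x)` voxel dimensions.
#' @param n_nuclei number of nuclei; centres are rejection-sampled at
#'   least `2 * nucleus_radius[1]` apart.
#' @param nucleus_radius `(mean, sd)` radius in voxels.
#' @param gene_channels data frame with columns `name`,
#'   `rate_at_dorsal`, `rate_at_ventral` (expected puncta/nucleus at
#'   the two ends of the y axis; both >= 0).
#' @param psf_sigma Gaussian point-spread sigma in voxels.
#' @param background `(mean, sd)` background intensity (spot peak ~ 1).
#' @param local_brightness_cv coefficient of variation of the lognormal
#'   per-nucleus brightness factor.
#' @param channel_contrast_jitter log-sd of the lognormal per-channel
#'   amplitude factor.
#' @param voxel_size physical `(z, y, x)` voxel size.
#' @param seed integer RNG seed.
#' @return An object of class `SyntheticVolumeSpec`.
#' @export
synthetic_volume_spec <- function(shape = c(64, 256, 256),
                                  n_nuclei = 30,
                                  nucleus_radius = c(6, 0.8),
                                  gene_channels = data.frame(
                                    name = c("geneA", "geneB"),
                                    rate_at_dorsal = c(20, 2),
                                    rate_at_ventral = c(2, 20)),
                                  psf_sigma = 1.2,
                                  background = c(0.05, 0.01),
                                  local_brightness_cv = 0.2,
                                  channel_contrast_jitter = 0.1,
                                  voxel_size = c(1, 1, 1),
                                  seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_nuclei >= 0,
            nucleus_radius[1] > 0, psf_sigma > 0,
            is.data.frame(gene_channels),
            all(c("name", "rate_at_dorsal", "rate_at_ventral") %in%
                  names(gene_channels)))
  if (any(gene_channels$rate_at_dorsal < 0) ||
      any(gene_channels$rate_at_ventral < 0))
    stop("puncta rates must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius, gene_channels = gene_channels,
                 psf_sigma = psf_sigma, background = background,
                 local_brightness_cv = local_brightness_cv,
                 channel_contrast_jitter = channel_contrast_jitter,
                 voxel_size = as.numeric(voxel_size), seed = as.integer(seed)),
            class = "SyntheticVolumeSpec")
}

# rejection-sample nucleus centres >= min_dist apart, with a margin
sample_centres <- function(shape, n, min_dist, margin, max_attempts = 20000L) {
  centres <- matrix(NA_real_, 0, 3)
  attempts <- 0L
  lo <- pmin(margin, (shape - 1) / 2)
  hi <- shape - 1 - lo
  while (nrow(centres) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " nuclei under the spacing invariant; ",
           "volume too small", call. = FALSE)
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
              runif(1, lo[3], hi[3]))
    if (nrow(centres) == 0 ||
        all(sqrt(colSums((t(centres) - cand)^2)) >= min_dist))
      centres <- rbind(centres, cand)
  }
  unname(centres)
}

# uniform points inside a sphere (rejection from the bounding cube)
runif_ball <- function(n, radius) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    cand <- matrix(runif(3 * m, -radius, radius), ncol = 3)
    keep <- rowSums(cand^2) <= radius^2
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic image volume with known nuclei and puncta
#'
#' The nuclear channel is a sum of Gaussian-blurred spheres at the true
#' centres, each scaled by a lognormal local-brightness factor, plus
#' Gaussian background noise. Each FISH channel renders the true puncta
#' (placed uniformly inside their parent nucleus, counts Poisson with a
#' rate linearly interpolated between `rate_at_ventral` (y = 0) and
#' `rate_at_dorsal` (y = max)) as PSF-sized spots scaled by a lognormal
#' per-channel contrast factor, plus background. Deterministic under
#' the spec seed.
#'
#' @param spec a [synthetic_volume_spec()].
#' @return list with `volume` (a [volume_stack()] with channels
#'   `"nuclei"` then one per gene) and `truth`, itself a list of
#'   `nuclei` (nucleus_id, z, y, x, radius, dv_position), `puncta`
#'   (gene, nucleus_id, z, y, x) and `counts` (nucleus_id, gene,
#'   true_count, dv_position).
#' @export
gen_volume <- function(spec) {
  stopifnot(inherits(spec, "SyntheticVolumeSpec"))
  set.seed(spec$seed)
  d <- spec$shape
  rmean <- spec$nucleus_radius[1]
  rsd <- if (length(spec$nucleus_radius) > 1) spec$nucleus_radius[2] else 0

  if (spec$n_nuclei > 0) {
    centres <- sample_centres(d, spec$n_nuclei, 2 * rmean,
                              margin = rmean + 3 * spec$psf_sigma)
    radii <- pmax(rnorm(spec$n_nuclei, rmean, rsd), 2)
    bright <- exp(rnorm(spec$n_nuclei, 0, spec$local_brightness_cv))
    dv <- centres[, 2] / max(d[2] - 1, 1)
  } else {
    centres <- matrix(NA_real_, 0, 3)
    radii <- bright <- dv <- numeric(0)
  }

  nuc <- array(0, d)
  for (i in seq_len(spec$n_nuclei)) {
    r <- radii[i]
    zi <- seq(max(1, floor(centres[i, 1] + 1 - r)), min(d[1], ceiling(centres[i, 1] + 1 + r)))
    yi <- seq(max(1, floor(centres[i, 2] + 1 - r)), min(d[2], ceiling(centres[i, 2] + 1 + r)))
    xi <- seq(max(1, floor(centres[i, 3] + 1 - r)), min(d[3], ceiling(centres[i, 3] + 1 + r)))
    dz2 <- (zi - 1 - centres[i, 1])^2
    dy2 <- (yi - 1 - centres[i, 2])^2
    dx2 <- (xi - 1 - centres[i, 3])^2
    inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2
    block <- nuc[zi, yi, xi, drop = FALSE]
    block[inside] <- pmax(block[inside], bright[i])
    nuc[zi, yi, xi] <- block
  }
  nuc <- gaussian_blur3d(nuc, spec$psf_sigma)
  nuc <- pmax(nuc + rnorm(length(nuc), spec$background[1], spec$background[2]), 0)
  dim(nuc) <- d

  genes <- spec$gene_channels
  puncta <- list()
  counts <- list()
  fish <- vector("list", nrow(genes))
  # amplitude that yields a post-blur peak of ~1 for an isolated punctum
  amp0 <- (2 * pi)^(3 / 2) * spec$psf_sigma^3
  for (gi in seq_len(nrow(genes))) {
    contrast <- exp(rnorm(1, 0, spec$channel_contrast_jitter))
    ch <- array(0, d)
    for (i in seq_len(spec$n_nuclei)) {
      rate <- genes$rate_at_ventral[gi] +
        (genes$rate_at_dorsal[gi] - genes$rate_at_ventral[gi]) * dv[i]
      k <- rpois(1, rate)
      counts[[length(counts) + 1L]] <- data.frame(
        nucleus_id = i, gene = genes$name[gi], true_count = k,
        dv_position = dv[i], stringsAsFactors = FALSE)
      if (k == 0) next
      pts <- sweep(runif_ball(k, radii[i] * 0.95), 2, centres[i, ], "+")
      puncta[[length(puncta) + 1L]] <- data.frame(
        gene = genes$name[gi], nucleus_id = i,
        z = pts[, 1], y = pts[, 2], x = pts[, 3], stringsAsFactors = FALSE)
      idx <- cbind(pmin(pmax(round(pts[, 1]) + 1, 1), d[1]),
                   pmin(pmax(round(pts[, 2]) + 1, 1), d[2]),
                   pmin(pmax(round(pts[, 3]) + 1, 1), d[3]))
      for (p in seq_len(k)) ch[idx[p, , drop = FALSE]] <- ch[idx[p, , drop = FALSE]] + amp0
    }
    ch <- gaussian_blur3d(ch, spec$psf_sigma) * contrast
    ch <- pmax(ch + rnorm(length(ch), spec$background[1], spec$background[2]), 0)
    dim(ch) <- d
    fish[[gi]] <- ch
  }

  arr <- array(0, c(d, 1L + nrow(genes)))
  arr[, , , 1] <- nuc
  for (gi in seq_len(nrow(genes))) arr[, , , gi + 1L] <- fish[[gi]]
  vol <- volume_stack(arr, voxel_size = spec$voxel_size,
                      channels = c("nuclei", genes$name),
                      brain_id = sprintf("synthetic_brain_%d", spec$seed))

  truth <- list(
    nuclei = if (spec$n_nuclei > 0)
      data.frame(nucleus_id = seq_len(spec$n_nuclei),
                 z = centres[, 1], y = centres[, 2], x = centres[, 3],
                 radius = radii, dv_position = dv)
      else data.frame(nucleus_id = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), radius = numeric(0), dv_position = numeric(0)),
    puncta = if (length(puncta)) do.call(rbind, puncta)
      else data.frame(gene = character(0), nucleus_id = integer(0),
                      z = numeric(0), y = numeric(0), x = numeric(0)),
    counts = if (length(counts)) do.call(rbind, counts)
      else data.frame(nucleus_id = integer(0), gene = character(0),
                      true_count = integer(0), dv_position = numeric(0)))
  list(volume = vol, truth = truth)
}
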