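#' Detect FISH puncta and assign them to nuclei
#'
#' Puncta are local maxima of the scale-normalized negated LoG response
#' of a preprocessed FISH channel above `min_response` (with
#' non-maximum suppression at `log_sigma * sqrt(3)`). Each punctum is
#' assigned to the nucleus whose ball-dilated mask (radius
#' `dilation_radius`, physical units — the nucleus plus its immediate
#' surrounding volume) contains it; a punctum inside two dilated masks
#' goes to the nucleus with the nearer centre, and puncta outside all
#' dilated masks are left unassigned (and excluded from counts).
#'
#' @param arr preprocessed 3-D FISH channel `(z, y, x)`.
#' @param mask_labels nucleus instance-label array from
#'   [segment_nuclei()].
#' @param centres data frame of nucleus centres (`z`, `y`, `x`,
#'   0-based voxels), row i for nucleus i.
#' @param dilation_radius physical dilation radius ("immediate
#'   surrounding volume"); default 2.
#' @param log_sigma LoG scale in voxels (match the PSF).
#' @param min_response response threshold.
#' @param voxel_size physical `(z, y, x)` voxel size.
#' @return data frame with columns `punctum_id`, `z`, `y`, `x`,
#'   `response`, `nucleus_id` (`NA` when unassigned).
#' @export
detect_puncta <- function(arr, mask_labels, centres, dilation_radius = 2,
                          log_sigma = 0.7, min_response = 0.08,
                          voxel_size = c(1, 1, 1)) {
  stopifnot(identical(dim(arr), dim(mask_labels)))
  d <- dim(arr)
  empty <- data.frame(punctum_id = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), response = numeric(0),
                      nucleus_id = integer(0))
  if (max(arr) == 0) return(empty)
  resp <- neg_log_filter3d(arr, log_sigma)
  peaks <- log_peaks(resp, d, min_response, radius = log_sigma * sqrt(3),
                     voxel_size = voxel_size)
  if (nrow(peaks) == 0) return(empty)

  # voxel search radius covering the physical dilation radius
  rad <- ceiling(dilation_radius / voxel_size)
  nucleus_id <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    zi <- seq(max(1, peaks$z[i] + 1 - rad[1]), min(d[1], peaks$z[i] + 1 + rad[1]))
    yi <- seq(max(1, peaks$y[i] + 1 - rad[2]), min(d[2], peaks$y[i] + 1 + rad[2]))
    xi <- seq(max(1, peaks$x[i] + 1 - rad[3]), min(d[3], peaks$x[i] + 1 + rad[3]))
    block <- mask_labels[zi, yi, xi, drop = FALSE]
    if (all(block == 0)) next
    dz2 <- ((zi - 1 - peaks$z[i]) * voxel_size[1])^2
    dy2 <- ((yi - 1 - peaks$y[i]) * voxel_size[2])^2
    dx2 <- ((xi - 1 - peaks$x[i]) * voxel_size[3])^2
    dist2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    cand <- unique(block[block > 0 & dist2 <= dilation_radius^2])
    if (length(cand) == 0) next
    if (length(cand) == 1) {
      nucleus_id[i] <- cand
    } else {
      # inside several dilated masks: nearest centre, physical units
      dc <- (centres$z[cand] - peaks$z[i])^2 * voxel_size[1]^2 +
        (centres$y[cand] - peaks$y[i])^2 * voxel_size[2]^2 +
        (centres$x[cand] - peaks$x[i])^2 * voxel_size[3]^2
      nucleus_id[i] <- cand[which.min(dc)]
    }
  }
  data.frame(punctum_id = seq_len(nrow(peaks)), z = peaks$z, y = peaks$y,
             x = peaks$x, response = peaks$response, nucleus_id = nucleus_id)
}

#' Count puncta per nucleus and max-normalize per brain and gene
#'
#' Raw counts are tallied per (nucleus, gene); normalized counts divide
#' by the maximum raw count over nuclei within each (brain, gene), so
#' the per-brain per-gene maximum is 1 whenever any punctum was
#' detected, and an all-zero gene stays all-zero.
#'
#' @param puncta data frame with columns `nucleus_id` and `gene`
#'   (unassigned puncta, `nucleus_id = NA`, are excluded).
#' @param nucleus_ids integer vector of all nuclei to report (zero
#'   counts included).
#' @param brain_id specimen identifier.
#' @param genes optional character vector of genes to report; defaults
#'   to those present in `puncta`.
#' @return data frame of class `CountTable` with columns `brain_id`,
#'   `nucleus_id`, `gene`, `raw_count`, `normalized_count`.
#' @export
count_and_normalize <- function(puncta, nucleus_ids, brain_id = "brain_1",
                                genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(as.character(puncta$gene)))
  out <- expand.grid(nucleus_id = nucleus_ids, gene = genes,
                     stringsAsFactors = FALSE)
  assigned <- puncta[!is.na(puncta$nucleus_id), , drop = FALSE]
  if (nrow(assigned) > 0) {
    key <- paste(assigned$nucleus_id, assigned$gene)
    tab <- table(key)
    out$raw_count <- as.integer(tab[paste(out$nucleus_id, out$gene)])
    out$raw_count[is.na(out$raw_count)] <- 0L
  } else out$raw_count <- integer(nrow(out))
  out$normalized_count <- numeric(nrow(out))
  for (g in genes) {
    sel <- out$gene == g
    if (!any(sel)) next
    mx <- max(out$raw_count[sel])
    if (mx > 0) out$normalized_count[sel] <- out$raw_count[sel] / mx
  }
  out <- data.frame(brain_id = rep(brain_id, nrow(out)), out,
                    stringsAsFactors = FALSE)
  class(out) <- c("CountTable", "data.frame")
  out
}

#' Voxel-mask overlap volume
#'
#' Symmetric intersection volume of two voxel masks, in voxels and in
#' physical units; the voxel-mask reduction of an axo-dendritic
#' surface-overlap measurement.
#'
#' @param mask_a,mask_b logical arrays of identical shape.
#' @param voxel_size physical `(z, y, x)` voxel size.
#' @return list with `voxels` and `volume`.
#' @export
mask_overlap <- function(mask_a, mask_b, voxel_size = c(1, 1, 1)) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ", call. = FALSE)
  n <- sum(mask_a & mask_b)
  list(voxels = n, volume = n * prod(voxel_size))
}
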