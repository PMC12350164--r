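#' Energy-minimizing intensity threshold
#'
#' Finds the threshold `t*` minimizing the two-class piecewise-constant
#' intensity energy
#' `E(t) = sum_{I >= t} (I - mu_in(t))^2 + sum_{I < t} (I - mu_out(t))^2`,
#' the simplest energy whose minimizing level set is the optimal
#' surface separating a bright nucleus from its dimmer surround (its
#' minimizer coincides with the Otsu-optimal threshold). Candidate
#' thresholds are the distinct observed intensities; among ties the
#' smallest threshold is returned.
#'
#' @param values numeric vector of intensities (>= 2 distinct values).
#' @return list with `threshold` and `energy`; both `NA` for a
#'   constant input.
#' @export
energy_threshold <- function(values) {
  values <- values[is.finite(values)]
  u <- sort(unique(values))
  if (length(u) < 2) return(list(threshold = NA_real_, energy = NA_real_))
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # for candidate t = u[k] the "out" class is {x < t}; x is sorted, so its
  # size is the index of the first occurrence of u[k] minus one
  m <- match(u, x) - 1L
  ss_out <- ifelse(m > 0, cs2[m + 1] - cs[m + 1]^2 / pmax(m, 1), 0)
  n_in <- n - m
  s_in <- cs[n + 1] - cs[m + 1]
  s2_in <- cs2[n + 1] - cs2[m + 1]
  ss_in <- s2_in - s_in^2 / n_in
  energies <- ss_out + ss_in
  best <- which.min(energies)  # which.min returns the first (smallest t) tie
  list(threshold = u[best], energy = energies[best])
}

#' Segment one nucleus within its Voronoi cell
#'
#' Thresholds the cell's voxels at the [energy_threshold()] minimizer
#' and keeps the 6-connected component of the supra-threshold set
#' containing (or, failing that, nearest to) the seed centre.
#'
#' @param arr preprocessed 3-D nuclear channel `(z, y, x)`.
#' @param labels Voronoi label array from [partition_voronoi()].
#' @param cell_id which Voronoi cell to segment.
#' @param centre optional seed `(z, y, x)` 0-based voxel coordinates;
#'   defaults to the cell's brightest voxel.
#' @return list with `mask` (logical array, full volume shape) and
#'   `threshold` (`NA` with an empty mask for a constant cell).
#' @export
segment_nucleus <- function(arr, labels, cell_id, centre = NULL) {
  stopifnot(identical(dim(arr), dim(labels)))
  in_cell <- labels == cell_id
  if (!any(in_cell)) stop("empty Voronoi cell: ", cell_id, call. = FALSE)
  et <- energy_threshold(arr[in_cell])
  mask <- array(FALSE, dim(arr))
  if (is.na(et$threshold)) return(list(mask = mask, threshold = NA_real_))
  supra <- in_cell & (arr >= et$threshold)
  comp <- array(label_components3d(as.logical(supra), dim(arr)), dim(arr))
  if (is.null(centre)) {
    w <- which(in_cell)
    centre_idx <- w[which.max(arr[w])]
  } else {
    centre_idx <- round(centre[1]) + 1 +
      dim(arr)[1] * (round(centre[2]) + dim(arr)[2] * round(centre[3]))
  }
  target <- comp[centre_idx]
  if (is.na(target) || target == 0) {
    # seed not supra-threshold: take the component nearest to the seed
    w <- which(comp > 0)
    if (length(w) == 0) return(list(mask = mask, threshold = et$threshold))
    d <- dim(arr)
    z <- (w - 1) %% d[1]
    rest <- (w - 1) %/% d[1]
    y <- rest %% d[2]
    x <- rest %/% d[2]
    cz <- (centre_idx - 1) %% d[1]
    crest <- (centre_idx - 1) %/% d[1]
    cy <- crest %% d[2]
    cx <- crest %/% d[2]
    target <- comp[w[which.min((z - cz)^2 + (y - cy)^2 + (x - cx)^2)]]
  }
  mask[comp == target] <- TRUE
  list(mask = mask, threshold = et$threshold)
}

#' Segment every nucleus of a volume
#'
#' Runs [segment_nucleus()] for each detected centre and assembles a
#' single instance-label volume.
#'
#' @param arr preprocessed 3-D nuclear channel.
#' @param labels Voronoi label array.
#' @param centres data frame from [detect_nuclei()] (row i seeds cell i).
#' @return list with `mask_labels` (integer array; 0 = background,
#'   i = nucleus i) and `records` (data frame: nucleus_id, z, y, x,
#'   voxel_count, threshold, voronoi_cell_id).
#' @export
segment_nuclei <- function(arr, labels, centres) {
  n <- nrow(centres)
  mask_labels <- array(0L, dim(arr))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    s <- segment_nucleus(arr, labels, i,
                         centre = as.numeric(centres[i, c("z", "y", "x")]))
    mask_labels[s$mask] <- i
    rec[[i]] <- data.frame(nucleus_id = i, z = centres$z[i], y = centres$y[i],
                           x = centres$x[i], voxel_count = sum(s$mask),
                           threshold = s$threshold, voronoi_cell_id = i)
  }
  list(mask_labels = mask_labels, records = do.call(rbind, rec))
}
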