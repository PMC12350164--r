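#' Detect nucleus centres by Laplacian-of-Gaussian blob detection
#'
#' Centres are local maxima (26-neighbourhood) of the scale-normalized
#' negated LoG response above `min_response`, followed by non-maximum
#' suppression within a physical radius of `log_sigma * sqrt(3)` (the
#' blob radius matched by the filter scale). Results are sorted by
#' response, descending.
#'
#' @param arr preprocessed 3-D channel `(z, y, x)`.
#' @param log_sigma LoG scale in voxels; a sphere of radius r is best
#'   matched by `log_sigma = r / sqrt(3)`.
#' @param min_response response threshold (> 0).
#' @param voxel_size physical `(z, y, x)` voxel size used for the
#'   suppression distance.
#' @return data frame with columns `z`, `y`, `x` (0-based voxel
#'   coordinates) and `response`; zero rows for an empty volume.
#' @export
detect_nuclei <- function(arr, log_sigma = 3.5, min_response = 0.1,
                          voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(arr)) == 3L, log_sigma > 0)
  empty <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      response = numeric(0))
  if (max(arr) == 0) return(empty)
  resp <- neg_log_filter3d(arr, log_sigma)
  peaks <- log_peaks(resp, dim(arr), min_response,
                     radius = log_sigma * sqrt(3), voxel_size = voxel_size)
  if (nrow(peaks) == 0) return(empty)
  peaks
}

# shared peak extraction: local maxima + greedy non-maximum suppression
log_peaks <- function(resp, d, min_response, radius, voxel_size) {
  idx <- local_maxima3d(as.numeric(resp), d, min_response)
  if (length(idx) == 0)
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      response = numeric(0)))
  z <- idx %% d[1]
  rest <- idx %/% d[1]
  y <- rest %% d[2]
  x <- rest %/% d[2]
  r <- resp[idx + 1]
  ord <- order(-r, z, y, x)
  z <- z[ord]; y <- y[ord]; x <- x[ord]; r <- r[ord]
  keep <- logical(length(r))
  pz <- z * voxel_size[1]; py <- y * voxel_size[2]; px <- x * voxel_size[3]
  for (i in seq_along(r)) {
    sel <- which(keep)
    if (length(sel) == 0 ||
        min((pz[sel] - pz[i])^2 + (py[sel] - py[i])^2 + (px[sel] - px[i])^2) >
          radius^2)
      keep[i] <- TRUE
  }
  data.frame(z = z[keep], y = y[keep], x = x[keep], response = r[keep])
}
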