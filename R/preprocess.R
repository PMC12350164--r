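#' Preprocessing parameters for volumetric channels
#'
#' The preprocessing cascade applied to each channel before detection:
#' quantile-clipped full-scale contrast stretching to `[0, 1]`, local
#' background removal by subtracting a 3-D Gaussian-blurred copy
#' (clipped at 0), a second full-scale stretch to recover contrast
#' lost to background removal, and a final 3-D median filter to remove
#' residual localized noise.
#'
#' @param gaussian_sigma background-removal Gaussian sigma in voxels;
#'   should be large relative to the structures of interest.
#' @param median_size odd median window edge length (1 = no filtering).
#' @param stretch_quantiles `(low, high)` clipping quantiles for the
#'   full-scale stretch, robust to hot pixels.
#' @return An object of class `PreprocessParams`.
#' @export
preprocess_params <- function(gaussian_sigma = 18, median_size = 3,
                              stretch_quantiles = c(0.001, 0.999)) {
  stopifnot(gaussian_sigma > 0, median_size >= 1, median_size %% 2 == 1,
            length(stretch_quantiles) == 2,
            stretch_quantiles[1] < stretch_quantiles[2],
            all(stretch_quantiles >= 0 & stretch_quantiles <= 1))
  structure(list(gaussian_sigma = gaussian_sigma,
                 median_size = as.integer(median_size),
                 stretch_quantiles = stretch_quantiles),
            class = "PreprocessParams")
}

stretch_full_scale <- function(arr, quantiles) {
  q <- quantile(arr, quantiles, names = FALSE)
  if (q[2] <= q[1]) {
    # constant (or near-constant) channel: flag and return zeros
    message("contrast stretch: constant-intensity input, returning zeros")
    return(array(0, dim(arr)))
  }
  array(pmin(pmax((arr - q[1]) / (q[2] - q[1]), 0), 1), dim(arr))
}

#' Preprocess one channel of a volume
#'
#' Applies, in order: quantile-clipped full-scale stretch to `[0, 1]`,
#' subtraction of a Gaussian-blurred copy (clipped at 0), a second
#' full-scale stretch, and a 3-D median filter. A constant-intensity
#' input yields an all-zero volume (with a message) rather than an
#' error.
#'
#' @param arr 3-D numeric array `(z, y, x)`, one channel.
#' @param params a [preprocess_params()].
#' @return array of the same shape with values in `[0, 1]`.
#' @export
preprocess_channel <- function(arr, params = preprocess_params()) {
  stopifnot(inherits(params, "PreprocessParams"), length(dim(arr)) == 3L)
  out <- stretch_full_scale(arr, params$stretch_quantiles)
  if (max(out) == 0) return(out)
  out <- pmax(out - gaussian_blur3d(out, params$gaussian_sigma), 0)
  dim(out) <- dim(arr)
  out <- stretch_full_scale(out, params$stretch_quantiles)
  if (max(out) == 0) return(out)
  median_filter3d(out, params$median_size)
}
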