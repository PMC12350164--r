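# Low-level separable 3-D filters wrapping the compiled kernels.
# All take/return plain 3-D arrays with dim (z, y, x).

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# second derivative of a Gaussian; used for the scale-normalized LoG
gaussian_d2_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  (x^2 / sigma^4 - 1 / sigma^2) * g
}

#' 3-D Gaussian blur (separable)
#'
#' @param arr 3-D numeric array `(z, y, x)`.
#' @param sigma standard deviation in voxels; scalar or length-3 `(z, y, x)`.
#' @return blurred array of the same shape.
#' @export
gaussian_blur3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3L, all(sigma > 0))
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  out <- as.numeric(arr)
  for (ax in 0:2) {
    out <- conv3d_axis(out, d, gaussian_kernel_1d(sigma[ax + 1L]), ax)
  }
  array(out, d)
}

# Scale-normalized negated Laplacian of Gaussian: positive response at
# bright blobs of radius ~ sigma*sqrt(3).
neg_log_filter3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3L, sigma > 0)
  d <- dim(arr)
  g <- gaussian_kernel_1d(sigma)
  g2 <- gaussian_d2_kernel_1d(sigma)
  acc <- array(0, d)
  for (ax2 in 0:2) {
    term <- as.numeric(arr)
    for (ax in 0:2) {
      k <- if (ax == ax2) g2 else g
      term <- conv3d_axis(term, d, k, ax)
    }
    acc <- acc + array(term, d)
  }
  -sigma^2 * acc
}

median_filter3d <- function(arr, size) {
  stopifnot(length(dim(arr)) == 3L, size >= 1, size %% 2 == 1)
  if (size == 1) return(arr)
  array(median3d(as.numeric(arr), dim(arr), as.integer(size)), dim(arr))
}
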