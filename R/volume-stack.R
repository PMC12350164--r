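#' Multi-channel 3-D intensity volume
#'
#' A `VolumeStack` is the carrier for all volumetric operations: a
#' non-negative intensity array with dimensions `(z, y, x, channel)`,
#' a physical voxel size and ordered channel labels. The y axis is, by
#' convention, the dorsoventral axis of the tissue (larger y = more
#' dorsal); this convention is recorded in the object and used by the
#' synthetic generator when laying down spatial gradients.
#'
#' @param data numeric array, either 3-D `(z, y, x)` (a single channel)
#'   or 4-D `(z, y, x, channel)`. All intensities must be finite and
#'   non-negative.
#' @param voxel_size numeric length-3, physical size of a voxel along
#'   `(z, y, x)`; units are arbitrary but must be consistent.
#' @param channels character vector of channel labels, one per channel.
#' @param brain_id single string identifying the specimen.
#'
#' @return An object of class `VolumeStack`.
#' @export
volume_stack <- function(data, voxel_size = c(1, 1, 1),
                         channels = NULL, brain_id = "brain_1") {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("`data` must be a 3-D or 4-D array", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("all intensities must be finite and >= 0", call. = FALSE)
  nc <- dim(data)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    stop("channel count does not match labels", call. = FALSE)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         channels = as.character(channels), brain_id = brain_id,
         dv_axis = "y"),
    class = "VolumeStack")
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VolumeStack '%s': %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              x$brain_id, d[1], d[2], d[3], d[4]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  voxel size (z,y,x):", paste(x$voxel_size, collapse = " x "), "\n")
  invisible(x)
}

#' Extract one channel of a VolumeStack as a 3-D array
#'
#' @param vol a [volume_stack()].
#' @param channel channel label or index.
#' @return 3-D numeric array `(z, y, x)`.
#' @export
get_channel <- function(vol, channel) {
  stopifnot(inherits(vol, "VolumeStack"))
  if (is.character(channel)) {
    i <- match(channel, vol$channels)
    if (is.na(i)) stop("unknown channel: ", channel, call. = FALSE)
  } else i <- as.integer(channel)
  arr <- vol$data[, , , i, drop = FALSE]
  dim(arr) <- dim(vol$data)[1:3]
  arr
}

#' Write / read a VolumeStack as multi-page TIFF plus JSON sidecar
#'
#' Volumes are stored as 16-bit multi-page grayscale TIFF with z the
#' fastest-varying page index and channel the slowest, alongside a JSON
#' sidecar (`<path>.json`) holding voxel size, channel labels, brain id
#' and the intensity scale used for the integer encoding.
#'
#' @param vol a [volume_stack()].
#' @param path output TIFF path.
#' @return `write_volume` returns `path` invisibly; `read_volume`
#'   returns a [volume_stack()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "VolumeStack"))
  d <- dim(vol$data)
  mx <- max(vol$data)
  scale <- if (mx > 0) mx else 1
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[1])) {
      pages[[k]] <- vol$data[z, , , ch] / scale
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel_size = vol$voxel_size, channels = vol$channels,
               brain_id = vol$brain_id, dv_axis = vol$dv_axis,
               shape_zyx = d[1:3], n_channels = d[4], intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape_zyx)
  nc <- as.integer(meta$n_channels)
  arr <- array(0, c(d, nc))
  k <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(d[1])) {
      arr[z, , , ch] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  volume_stack(arr, voxel_size = meta$voxel_size, channels = meta$channels,
               brain_id = meta$brain_id)
}
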