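#' Partition a volume into 3-D Voronoi cells around detected centres
#'
#' Every voxel is labelled with the index (1-based, row order of
#' `centres`) of its nearest centre under Euclidean distance in
#' physical units. Ties are broken in favour of the lowest centre
#' index.
#'
#' @param centres data frame or matrix with columns `z`, `y`, `x`
#'   (0-based voxel coordinates), one row per seed; at least one.
#' @param shape integer length-3 `(z, y, x)` voxel dimensions.
#' @param voxel_size physical `(z, y, x)` voxel size.
#' @return integer array of shape `shape` with values in
#'   `1:nrow(centres)`.
#' @export
partition_voronoi <- function(centres, shape, voxel_size = c(1, 1, 1)) {
  cm <- as.matrix(as.data.frame(centres)[, c("z", "y", "x")])
  if (nrow(cm) == 0) stop("at least one centre is required", call. = FALSE)
  lab <- nearest_centre_labels(as.integer(shape), cm, as.numeric(voxel_size))
  array(lab, shape)
}
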