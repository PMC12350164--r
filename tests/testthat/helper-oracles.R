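# Independent brute-force oracles used to validate the fast
# implementations. Deliberately naive: direct loops and enumeration.

# nearest-centre assignment by exhaustive per-voxel search
oracle_voronoi <- function(centres, shape, voxel_size = c(1, 1, 1)) {
  lab <- array(0L, shape)
  for (x in seq_len(shape[3])) for (y in seq_len(shape[2]))
    for (z in seq_len(shape[1])) {
      d2 <- (centres$z - (z - 1))^2 * voxel_size[1]^2 +
        (centres$y - (y - 1))^2 * voxel_size[2]^2 +
        (centres$x - (x - 1))^2 * voxel_size[3]^2
      lab[z, y, x] <- which.min(d2)  # first minimum = lowest index
    }
  lab
}

# exhaustive minimization of the two-class energy over all observed values
oracle_energy_threshold <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2) return(NA_real_)
  en <- vapply(u, function(t) {
    inside <- values[values >= t]
    outside <- values[values < t]
    e_in <- sum((inside - mean(inside))^2)
    e_out <- if (length(outside)) sum((outside - mean(outside))^2) else 0
    e_in + e_out
  }, numeric(1))
  u[which.min(en)]
}

# nested-loop per-neuron synapse totals
oracle_totals <- function(adj, type, side = "source", partner = NULL) {
  ids <- if (side == "source") adj$source_id else adj$target_id
  keep <- if (side == "source") adj$source_type == type else adj$target_type == type
  if (!is.null(partner))
    keep <- keep & (if (side == "source") adj$target_type else adj$source_type) == partner
  u <- sort(unique(ids[keep]))
  tot <- numeric(length(u))
  for (i in seq_along(u)) {
    s <- 0
    for (r in seq_len(nrow(adj))) if (keep[r] && ids[r] == u[i])
      s <- s + adj$synapse_count[r]
    tot[i] <- s
  }
  data.frame(neuron_id = u, total = tot)
}

# exact one-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_less <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combos <- combn(length(pooled), n)
  us <- apply(combos, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(us <= u_obs + 1e-9)
}

# direct 2-D Gaussian convolution with replicate boundary (for the
# normalized-convolution heatmap smoother)
oracle_smooth2d <- function(m, sigma = 1) {
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  valid <- !is.na(m)
  v <- m; v[!valid] <- 0
  conv <- function(mat) {
    out <- matrix(0, nrow(mat), ncol(mat))
    for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
      acc <- 0
      for (di in -r:r) for (dj in -r:r) {
        ii <- min(max(i + di, 1), nrow(mat))
        jj <- min(max(j + dj, 1), ncol(mat))
        acc <- acc + k1[di + r + 1] * k1[dj + r + 1] * mat[ii, jj]
      }
      out[i, j] <- acc
    }
    out
  }
  num <- conv(v); den <- conv(valid * 1)
  out <- num / den
  out[den < 1e-12] <- NA
  out
}

# small default volume spec for fast unit tests
small_volume_spec <- function(seed = 1L, ...) {
  synthetic_volume_spec(shape = c(32, 96, 96), n_nuclei = 6,
                        nucleus_radius = c(5, 0.5),
                        gene_channels = data.frame(
                          name = "geneA", rate_at_dorsal = 12,
                          rate_at_ventral = 2),
                        seed = seed, ...)
}
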