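test_that("preprocessing cascade behaves on degenerate and simple inputs", {
  # constant volume -> all zeros, not an error
  const <- array(0.7, c(8, 8, 8))
  expect_message(out <- preprocess_channel(const, preprocess_params(
    gaussian_sigma = 2, median_size = 1)), "constant")
  expect_true(all(out == 0))

  # single bright voxel on zero background stretches to full scale
  v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 3
  out <- preprocess_channel(v, preprocess_params(gaussian_sigma = 2,
                                                 median_size = 1,
                                                 stretch_quantiles = c(0, 1)))
  expect_equal(max(out), 1)
  expect_equal(which.max(out), which.max(v))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("preprocessing suppresses background on generated data", {
  sim <- gen_volume(small_volume_spec(seed = 3))
  ch <- get_channel(sim$volume, "nuclei")
  out <- preprocess_channel(ch, preprocess_params(gaussian_sigma = 15))
  # voxels far from any nucleus should be near zero after preprocessing
  lab <- array(TRUE, dim(ch))
  tru <- sim$truth$nuclei
  idx <- which(lab, arr.ind = TRUE)
  d2min <- rep(Inf, nrow(idx))
  for (i in seq_len(nrow(tru)))
    d2min <- pmin(d2min, (idx[, 1] - 1 - tru$z[i])^2 +
                    (idx[, 2] - 1 - tru$y[i])^2 + (idx[, 3] - 1 - tru$x[i])^2)
  bg <- out[d2min > (2 * 5)^2]
  expect_lt(median(bg), 0.05)
})

test_that("LoG detection finds isolated and packed nuclei", {
  expect_equal(nrow(detect_nuclei(array(0, c(8, 8, 8)))), 0)

  # one synthetic sphere: one centre within 2 voxels of truth
  one <- synthetic_volume_spec(shape = c(32, 32, 32), n_nuclei = 1,
                               nucleus_radius = c(5, 0), background = c(0, 0),
                               local_brightness_cv = 0, seed = 4)
  sim <- gen_volume(one)
  ch <- preprocess_channel(get_channel(sim$volume, "nuclei"),
                           preprocess_params(gaussian_sigma = 15))
  cen <- detect_nuclei(ch, log_sigma = 5 / sqrt(3), min_response = 0.05)
  expect_equal(nrow(cen), 1)
  tru <- sim$truth$nuclei
  expect_lt(sqrt((cen$z - tru$z)^2 + (cen$y - tru$y)^2 + (cen$x - tru$x)^2), 2)

  # small multi-nucleus fixture: perfect detection at matched scale
  sim6 <- gen_volume(small_volume_spec(seed = 5))
  ch6 <- preprocess_channel(get_channel(sim6$volume, "nuclei"),
                            preprocess_params(gaussian_sigma = 15))
  cen6 <- detect_nuclei(ch6, log_sigma = 5 / sqrt(3), min_response = 0.1)
  expect_equal(nrow(cen6), 6)
})

test_that("Voronoi partition equals the exhaustive nearest-centre oracle", {
  set.seed(10)
  for (rep in 1:3) {
    shape <- c(12, 15, 10)
    centres <- data.frame(z = runif(4, 0, shape[1] - 1),
                          y = runif(4, 0, shape[2] - 1),
                          x = runif(4, 0, shape[3] - 1))
    vs <- c(2, 1, 1.5)
    expect_identical(partition_voronoi(centres, shape, vs),
                     oracle_voronoi(centres, shape, vs))
  }
  # single centre -> uniform label; tie at midpoint goes to centre 1
  expect_true(all(partition_voronoi(data.frame(z = 1, y = 1, x = 1),
                                    c(4, 4, 4)) == 1L))
  two <- partition_voronoi(data.frame(z = c(0, 4), y = c(2, 2), x = c(2, 2)),
                           c(5, 5, 5))
  expect_identical(two[3, 3, 3], 1L)  # equidistant voxel -> lowest index
  expect_error(partition_voronoi(data.frame(z = numeric(0), y = numeric(0),
                                            x = numeric(0)), c(4, 4, 4)))
})

test_that("energy threshold equals exhaustive minimization", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- sample(round(runif(200), 2))
    expect_equal(energy_threshold(vals)$threshold,
                 oracle_energy_threshold(vals))
  }
  # noiseless two-level cell separates exactly
  expect_equal(energy_threshold(c(rep(0.1, 50), rep(0.8, 20)))$threshold, 0.8)
  expect_true(is.na(energy_threshold(rep(0.5, 30))$threshold))
})

test_that("segmentation recovers a noiseless two-level sphere exactly", {
  shape <- c(24, 24, 24)
  arr <- array(0.1, shape)
  truth <- array(FALSE, shape)
  for (z in 1:24) for (y in 1:24) for (x in 1:24)
    if ((z - 12)^2 + (y - 12)^2 + (x - 12)^2 <= 36) {
      arr[z, y, x] <- 0.8; truth[z, y, x] <- TRUE
    }
  labels <- array(1L, shape)
  s <- segment_nucleus(arr, labels, 1, centre = c(11, 11, 11))
  expect_identical(s$mask, truth)
  expect_equal(s$threshold, 0.8)
  # constant cell: empty mask, missing threshold
  flat <- segment_nucleus(array(0.3, c(6, 6, 6)), array(1L, c(6, 6, 6)), 1)
  expect_true(is.na(flat$threshold))
  expect_false(any(flat$mask))
})

test_that("segmentation masks overlap the true nuclei well", {
  sim <- gen_volume(small_volume_spec(seed = 6))
  ch <- preprocess_channel(get_channel(sim$volume, "nuclei"),
                           preprocess_params(gaussian_sigma = 15))
  cen <- detect_nuclei(ch, log_sigma = 5 / sqrt(3), min_response = 0.1)
  voro <- partition_voronoi(cen, dim(ch))
  seg <- segment_nuclei(ch, voro, cen)
  tru <- sim$truth$nuclei
  # match each true nucleus to the nearest detected centre, compute IoU
  ious <- vapply(seq_len(nrow(tru)), function(i) {
    d2 <- (cen$z - tru$z[i])^2 + (cen$y - tru$y[i])^2 + (cen$x - tru$x[i])^2
    lab <- which.min(d2)
    grid <- which(array(TRUE, dim(ch)), arr.ind = TRUE)
    truth_mask <- (grid[, 1] - 1 - tru$z[i])^2 + (grid[, 2] - 1 - tru$y[i])^2 +
      (grid[, 3] - 1 - tru$x[i])^2 <= tru$radius[i]^2
    got <- as.vector(seg$mask_labels == lab)
    sum(truth_mask & got) / sum(truth_mask | got)
  }, numeric(1))
  expect_gte(mean(ious), 0.7)
})

test_that("puncta detection assigns spots to the right nuclei", {
  # channel all zeros -> no puncta
  z <- array(0, c(8, 8, 8))
  expect_equal(nrow(detect_puncta(z, array(0L, c(8, 8, 8)),
                                  data.frame(z = 1, y = 1, x = 1))), 0)

  sim <- gen_volume(small_volume_spec(seed = 7))
  tab <- quantify_volume(sim$volume, quantify_config(
    preprocess_nuclei = preprocess_params(gaussian_sigma = 15),
    log_sigma_nuclei = 5 / sqrt(3)))
  qc <- attr(tab, "qc")
  expect_equal(qc$n_nuclei, 6)
  # counts correlate strongly with truth
  cen <- attr(tab, "nuclei")
  tru <- sim$truth$nuclei
  at <- vapply(seq_len(nrow(cen)), function(i)
    which.min((tru$z - cen$z[i])^2 + (tru$y - cen$y[i])^2 +
                (tru$x - cen$x[i])^2), integer(1))
  cts <- sim$truth$counts
  got <- tab[tab$gene == "geneA", ]
  expect_gt(cor(got$raw_count,
                cts$true_count[match(at[got$nucleus_id], cts$nucleus_id)],
                method = "spearman"), 0.8)
})

test_that("raising the puncta threshold never increases the count", {
  sim <- gen_volume(small_volume_spec(seed = 8))
  ch <- preprocess_channel(get_channel(sim$volume, "geneA"),
                           preprocess_params(gaussian_sigma = 5,
                                             median_size = 1))
  labels <- array(1L, dim(ch))
  centres <- data.frame(z = 16, y = 48, x = 48)
  n_prev <- Inf
  for (thr in c(0.02, 0.05, 0.1, 0.2)) {
    n <- nrow(detect_puncta(ch, labels, centres, dilation_radius = 100,
                            min_response = thr))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("count normalization follows the per-brain per-gene max rule", {
  p <- data.frame(nucleus_id = c(rep(1, 2), rep(2, 5), rep(3, 10)),
                  gene = "g")
  tab <- count_and_normalize(p, 1:3, "b1")
  expect_equal(tab$raw_count, c(2L, 5L, 10L))
  expect_equal(tab$normalized_count, c(0.2, 0.5, 1.0))
  # single nucleus -> normalized 1
  one <- count_and_normalize(data.frame(nucleus_id = 1, gene = "g"), 1)
  expect_equal(one$normalized_count, 1)
  # all-zero gene stays all zero; per-gene max is 1 otherwise
  two <- count_and_normalize(p, 1:3, genes = c("g", "empty"))
  expect_true(all(two$normalized_count[two$gene == "empty"] == 0))
  expect_equal(max(two$normalized_count[two$gene == "g"]), 1)
})

test_that("mask overlap equals the brute-force voxel AND", {
  set.seed(12)
  a <- array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6))
  b <- array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6))
  ov <- mask_overlap(a, b, voxel_size = c(1, 2, 0.5))
  brute <- 0
  for (i in seq_along(a)) if (a[i] && b[i]) brute <- brute + 1
  expect_equal(ov$voxels, brute)
  expect_equal(ov$volume, brute * 1 * 2 * 0.5)
  expect_equal(mask_overlap(a, b), mask_overlap(b, a))
  expect_equal(mask_overlap(a, a)$voxels, sum(a))
  expect_equal(mask_overlap(a, !a)$voxels, 0)
  expect_error(mask_overlap(a, array(TRUE, c(2, 2, 2))), "shape")
})

test_that("the pipeline is deterministic and round-trips through TIFF", {
  sim <- gen_volume(small_volume_spec(seed = 9))
  cfg <- quantify_config(preprocess_nuclei = preprocess_params(
    gaussian_sigma = 15), log_sigma_nuclei = 5 / sqrt(3))
  t1 <- quantify_volume(sim$volume, cfg)
  t2 <- quantify_volume(sim$volume, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  path <- file.path(tempdir(), "vol.tiff")
  write_volume(sim$volume, path)
  back <- read_volume(path)
  expect_equal(back$channels, sim$volume$channels)
  expect_equal(back$data, sim$volume$data, tolerance = 1e-3)
  unlink(c(path, paste0(path, ".json")))
})
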