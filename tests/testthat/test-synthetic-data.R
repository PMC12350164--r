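test_that("expression generator is deterministic and respects the latent axis", {
  spec <- gradient_population_spec(n_cells = 300, seed = 11)
  a <- gen_expression(spec)
  b <- gen_expression(spec)
  expect_identical(a, b)
  expect_true(all(a$truth$position >= 0 & a$truth$position <= 1))
  expect_equal(a$cell_meta$coverage, unname(rowSums(a$counts)))

  # no gradient signal when all coefficients are zero
  flat <- gradient_population_spec(
    n_cells = 600,
    genes = default_gradient_genes(coef = 0), seed = 3)
  s <- gen_expression(flat)
  rs <- apply(s$counts, 2, function(v)
    suppressWarnings(cor(v, s$truth$position, method = "spearman")))
  expect_true(all(abs(rs) < 0.1))

  # antiparallel construction: opposite-coefficient genes anticorrelate
  anti <- gen_expression(gradient_population_spec(
    n_cells = 600,
    genes = data.frame(name = c("up", "down"), baseline_mean = 20,
                       gradient_coef = c(2, -2), dispersion = 5),
    seed = 4))
  expect_lt(cor(anti$counts[, "up"], anti$counts[, "down"],
                method = "spearman"), 0)
})

test_that("expression generator enforces discrete-cluster structure", {
  s <- gen_expression(gradient_population_spec(n_cells = 200, n_clusters = 2,
                                               seed = 5))
  expect_identical(sort(unique(s$truth$position)), c(0, 1))
  expect_error(gradient_population_spec(n_clusters = 1))
  expect_error(gradient_population_spec(
    genes = data.frame(name = "g", baseline_mean = 1, gradient_coef = 1,
                       dispersion = 0)))
})

test_that("NB counts match the specified moments", {
  mu <- 20; disp <- 5
  s <- gen_expression(gradient_population_spec(
    n_cells = 2000,
    genes = data.frame(name = "g", baseline_mean = mu, gradient_coef = 0,
                       dispersion = disp),
    coverage_sdlog = 0, seed = 8))
  x <- s$counts[, 1]
  n <- length(x)
  expect_lt(abs(mean(x) - mu), 3 * sqrt((mu + mu^2 / disp) / n))
  # variance check within 3 standard errors (approximate SE via 4th moment)
  v <- var(x)
  se_v <- sqrt((mean((x - mean(x))^4) - v^2) / n)
  expect_lt(abs(v - (mu + mu^2 / disp)), 3 * se_v)
})

test_that("volume generator ships consistent truth and honours invariants", {
  sim <- gen_volume(small_volume_spec(seed = 2))
  tru <- sim$truth$nuclei
  expect_equal(nrow(tru), 6)
  # pairwise spacing >= 2 x mean radius
  d <- as.matrix(dist(tru[, c("z", "y", "x")]))
  expect_true(all(d[upper.tri(d)] >= 2 * 5))
  # puncta lie inside their parent nucleus
  p <- sim$truth$puncta
  for (i in seq_len(nrow(p))) {
    nuc <- tru[tru$nucleus_id == p$nucleus_id[i], ]
    expect_lte(sqrt((p$z[i] - nuc$z)^2 + (p$y[i] - nuc$y)^2 +
                      (p$x[i] - nuc$x)^2), nuc$radius)
  }
  # per-nucleus counts in the truth table match the rendered puncta
  tab <- table(sim$truth$puncta$nucleus_id)
  cts <- sim$truth$counts
  expect_equal(unname(cts$true_count[match(names(tab), cts$nucleus_id)]),
               unname(as.integer(tab)))
  expect_true(all(sim$volume$data >= 0))
  # determinism
  expect_identical(gen_volume(small_volume_spec(seed = 2))$truth, sim$truth)
})

test_that("volume generator handles degenerate specs", {
  none <- gen_volume(synthetic_volume_spec(shape = c(16, 32, 32),
                                           n_nuclei = 0, seed = 1))
  expect_equal(nrow(none$truth$nuclei), 0)
  expect_equal(nrow(none$truth$puncta), 0)
  # channels are pure background
  expect_lt(max(none$volume$data), 0.2)
  # impossible packing errors out
  expect_error(gen_volume(synthetic_volume_spec(shape = c(16, 20, 20),
                                                n_nuclei = 40, seed = 1)),
               "spacing")
})

test_that("flat puncta rate gives a slope CI containing zero on truth", {
  spec <- synthetic_volume_spec(
    shape = c(32, 128, 128), n_nuclei = 12,
    nucleus_radius = c(5, 0.5),
    gene_channels = data.frame(name = "g", rate_at_dorsal = 5,
                               rate_at_ventral = 5),
    seed = 9)
  sim <- gen_volume(spec)
  cts <- sim$truth$counts
  fit <- lm(cts$true_count ~ cts$dv_position)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("connectome generator recovers its own moments and pairing", {
  con <- gen_connectome(synthetic_connectome_spec(n_source = 200, slope = 0,
                                                  intercept = 10, seed = 1))
  expect_lt(abs(mean(con$adjacency$synapse_count) - 10), 1)
  pair <- gen_connectome(synthetic_connectome_spec(antiparallel_pair = TRUE,
                                                   seed = 2))
  expect_setequal(unique(pair$adjacency$source_type), c("typeA", "typeB"))
  # both types share positions
  pos <- pair$positions
  expect_equal(pos$dv_position[grepl("typeA", pos$neuron_id)],
               pos$dv_position[grepl("typeB", pos$neuron_id)])
  expect_identical(gen_connectome(synthetic_connectome_spec(seed = 3)),
                   gen_connectome(synthetic_connectome_spec(seed = 3)))
})

test_that("takeoff generator respects the 7 ms mode boundary", {
  all_short <- gen_takeoffs(synthetic_behavior_spec(p_short = 1, seed = 1))
  expect_true(all(all_short$duration_ms <= 7))
  all_long <- gen_takeoffs(synthetic_behavior_spec(p_short = 0, seed = 1))
  expect_true(all(all_long$duration_ms > 7))
  expect_true(all(classify_takeoff(all_long$duration_ms) == "long"))
  mix <- gen_takeoffs(synthetic_behavior_spec(seed = 2))
  expect_identical(classify_takeoff(mix$duration_ms), mix$true_mode)
})

test_that("tuning generator encodes the target DSI exactly when noiseless", {
  spec <- synthetic_tuning_spec(dsi_by_position = c(0.5, -0.3),
                                trace_noise_sd = 0, seed = 1)
  sim <- gen_tuning_traces(spec)
  expect_length(sim[[1]]$traces, 24)
  r1 <- directional_tuning(sim[[1]]$traces)
  expect_equal(r1$dsi, 0.5, tolerance = 1e-6)
  r2 <- directional_tuning(sim[[2]]$traces)
  expect_equal(r2$dsi, -0.3, tolerance = 1e-6)
  # zero target DSI recovered within noise tolerance at the default noise
  z <- gen_tuning_traces(synthetic_tuning_spec(
    positions = data.frame(id = "p", dv_class = "dorsal"),
    dsi_by_position = 0, seed = 3))
  expect_lt(abs(directional_tuning(z[[1]]$traces)$dsi), 0.05)
  expect_error(synthetic_tuning_spec(response_amplitude = 0,
                                     dsi_by_position = c(1, 0)))
})
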