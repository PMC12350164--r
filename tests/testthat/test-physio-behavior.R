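test_that("loom profile follows the time-to-contact geometry", {
  t <- seq(0, 0.7, by = 0.005)
  lp <- loom_profile(t, l = 0.5, v = 62.5, start_distance = 50)
  expect_equal(lp$l_over_v_ms, 8)
  expect_false(lp$truncated)
  expect_true(all(diff(lp$theta_deg) > 0))  # strictly increasing pre-contact
  expect_true(all(lp$theta_deg > 0 & lp$theta_deg < 180))
  # l / (v * tau) = 1  =>  theta = 90 degrees
  lp90 <- loom_profile(0, l = 5, v = 1, start_distance = 5)
  expect_equal(lp90$theta_deg, 90)
  # truncation at contact is flagged
  lt <- loom_profile(seq(0, 1, 0.01), l = 0.5, v = 62.5, start_distance = 50)
  expect_true(lt$truncated)
  # constant-angular-rate ramp: 0 -> 30 deg at 500 deg/s
  tr <- seq(0, 0.1, by = 0.001)
  ramp <- loom_profile(tr, kind = "constant_angular_rate")
  expect_equal(ramp$theta_deg, pmin(500 * tr, 30))
})

test_that("dF/F normalizes against the pre-onset baseline", {
  tm <- seq(0, 2, by = 0.01)
  flat <- list(time = tm, F = rep(5, length(tm)), onset = 1)
  expect_true(all(dff(flat) == 0))
  doubled <- list(time = tm, F = ifelse(tm >= 1, 10, 5), onset = 1)
  d <- dff(doubled)
  expect_equal(max(d), 1)
  expect_error(dff(list(time = tm, F = rep(0, length(tm)), onset = 1)),
               "F0")
  # known amplitude recovered from a generated trace
  sim <- gen_tuning_traces(synthetic_tuning_spec(
    positions = data.frame(id = "p", dv_class = "dorsal"),
    dsi_by_position = 0.5, trace_noise_sd = 0.005, seed = 40))
  tr <- sim[[1]]$traces[[1]]  # 0 degrees: amplitude = 1.5
  expect_equal(max(dff(tr)), 1.5, tolerance = 0.05)
})

test_that("DSI hits its endpoints and stays bounded", {
  mk <- function(r_up, r_down) {
    tm <- seq(0, 4, by = 1 / 9)
    bump <- exp(-(tm - 1.25)^2 / (2 * 0.15^2))
    lapply(seq(0, 345, 15), function(th) {
      a <- if (th == 0) r_up else if (th == 180) r_down else 0.1
      list(time = tm, F = 100 * (1 + a * bump), onset = 0.5, direction = th)
    })
  }
  expect_equal(directional_tuning(mk(2, 0))$dsi, 1)
  expect_equal(directional_tuning(mk(0, 2))$dsi, -1)
  expect_equal(directional_tuning(mk(1, 1))$dsi, 0, tolerance = 1e-6)
  expect_equal(directional_tuning(mk(3, 1))$dsi, 0.5, tolerance = 1e-6)
  expect_true(is.na(directional_tuning(mk(0, 0))$dsi))
  # bounded for random non-negative inputs
  set.seed(41)
  for (i in 1:5) {
    r <- directional_tuning(mk(runif(1, 0, 5), runif(1, 0, 5)))
    expect_true(r$dsi >= -1 && r$dsi <= 1)
  }
  expect_error(directional_tuning(mk(1, 1)[1:23]), "24")
})

test_that("bootstrap mean uses the seeded percentile machinery", {
  const <- bootstrap_mean(rep(3, 10), n_boot = 500, seed = 1)
  expect_equal(const$mean, 3)
  expect_equal(unname(diff(const$ci)), 0)
  expect_equal(formals(bootstrap_mean)$n_boot, 10000)
  # reproducibility under a fixed seed and identical input
  x <- rnorm(15)
  expect_identical(bootstrap_mean(x, n_boot = 500, seed = 3),
                   bootstrap_mean(x, n_boot = 500, seed = 3))
})

test_that("heatmap smoothing is a normalized convolution", {
  u <- matrix(0.4, 6, 6)
  expect_equal(dsi_heatmap(u), u)
  # single hot cell in a large all-valid grid: mass preserved
  m <- matrix(0, 11, 11); m[6, 6] <- 1
  sm <- dsi_heatmap(m)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # output range within input range
  set.seed(42)
  g <- matrix(runif(25, -1, 1), 5, 5); g[sample(25, 5)] <- NA
  sm2 <- dsi_heatmap(g)
  expect_true(all(sm2 >= min(g, na.rm = TRUE) - 1e-12 &
                    sm2 <= max(g, na.rm = TRUE) + 1e-12, na.rm = TRUE))
  # matches the direct convolution oracle on 5 x 5 grids
  expect_equal(sm2, oracle_smooth2d(g), tolerance = 1e-10)
  full <- matrix(rnorm(25), 5, 5)
  expect_equal(dsi_heatmap(full), oracle_smooth2d(full), tolerance = 1e-10)
  expect_error(dsi_heatmap(matrix(NA_real_, 3, 3)), "missing")
})

test_that("GF response summarizes peak and area against baseline", {
  tm <- seq(-3, 1, by = 0.001)
  flat <- list(time = tm, Vm = rep(-60, length(tm)))
  s <- gf_response(flat, onset = 0)
  expect_equal(s$peak, 0)
  expect_equal(s$area_ms_mv, 0)
  # rectangular 10 mV deflection covering the 150 ms window: area 1500
  rect <- list(time = tm, Vm = ifelse(tm >= 0 & tm <= 0.15, -50, -60))
  s2 <- gf_response(rect, onset = 0)
  expect_equal(s2$peak, 10)
  expect_equal(s2$area_ms_mv, 1500, tolerance = 15)
  # synthetic EPSP amplitude recovery
  epsp <- list(time = tm, Vm = -60 + 8 * exp(-(tm - 0.05)^2 / (2 * 0.01^2)))
  s3 <- gf_response(epsp, onset = 0)
  expect_equal(s3$peak, 8, tolerance = 0.05)
  expect_error(gf_response(flat, onset = 10), "window")
})

test_that("takeoff classification applies boundary and outlier rules", {
  expect_equal(classify_takeoff(c(5, 7, 7.01, 20)),
               c("short", "short", "long", "long"))
  expect_equal(classify_takeoff(55, outlier_cutoff = 50), "excluded")
  expect_equal(classify_takeoff(55), "long")  # rule off by default
  expect_error(classify_takeoff(c(5, -1)))
})

test_that("short-mode percentages and the elevation gradient test work", {
  rec <- data.frame(elevation = rep(c(0, 45), each = 10),
                    duration_ms = c(rep(5, 2), rep(10, 8),
                                    rep(5, 8), rep(10, 2)))
  sg <- shortmode_gradient(rec)
  expect_equal(sg$percentages$pct_short, c(20, 80))
  expect_true(all(sg$percentages$ci_lo <= sg$percentages$pct_short &
                    sg$percentages$pct_short <= sg$percentages$ci_hi))
  # identical proportions at large n: no gradient detected
  same <- data.frame(elevation = rep(c(0, 45, 77), each = 300),
                     duration_ms = rep(c(rep(5, 150), rep(10, 150)), 3))
  expect_gt(shortmode_gradient(same)$p, 0.5)
  # generated gradient detected
  tk <- gen_takeoffs(synthetic_behavior_spec(
    elevations = c(0, 45, 77), p_short = c(0.2, 0.5, 0.8),
    n_per_elevation = 100, seed = 43))
  sg2 <- shortmode_gradient(tk)
  expect_lt(sg2$p, 0.05)
  expect_equal(nrow(sg2$pairwise), 3)
  expect_true(all(sg2$pairwise$p_bonferroni >= sg2$pairwise$p_raw))
})

test_that("rank tests agree with exact enumeration at small n", {
  # disjoint samples, n = 3 vs 3: exact one-sided p = 1/20
  rt <- rank_tests(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(rt$p, 0.05)
  expect_equal(rt$p, oracle_mw_less(c(1, 2, 3), c(4, 5, 6)))
  # random small samples match full permutation
  set.seed(44)
  for (i in 1:5) {
    a <- round(rnorm(5), 2); b <- round(rnorm(6), 2)
    if (anyDuplicated(c(a, b))) next
    expect_equal(rank_tests(a, b, alternative = "less")$p,
                 oracle_mw_less(a, b))
  }
  # identical samples -> p near 1
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_gt(rank_tests(x, x)$p, 0.9)
  # multi-sample route
  k <- rank_tests(list(rnorm(10), rnorm(10) + 3, rnorm(10)))
  expect_equal(k$method, "Kruskal-Wallis")
  expect_equal(nrow(k$pairwise), 3)
})

test_that("takeoff percentages reproduce generator probabilities", {
  spec <- synthetic_behavior_spec(n_per_elevation = 200, seed = 45)
  tk <- gen_takeoffs(spec)
  sg <- shortmode_gradient(tk)
  # observed percentage within binomial 95% bounds of the generator p
  for (i in seq_along(spec$elevations)) {
    p <- spec$p_short[i]; n <- 200
    half <- 1.96 * sqrt(p * (1 - p) / n)
    expect_lt(abs(sg$percentages$pct_short[i] / 100 - p), half + 1e-9)
  }
})
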