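#' Looming-stimulus angular-size profile
#'
#' For a constant-approach loom, the full angular size of an object of
#' half-size `l` approaching at speed `v` is
#' `theta(t) = 2 * atan(l / (v * tau))` with `tau` the time to contact
#' `(start_distance - v * t) / v`; the profile is truncated (held at
#' 180 degrees and flagged) at contact. The expansion dynamics are
#' parameterized by the loom velocity `l/v`. For a
#' constant-angular-rate stimulus the size ramps linearly between the
#' start and end angles at `angular_rate` degrees per second.
#'
#' @param t numeric vector of times (s).
#' @param kind `"constant_approach"` or `"constant_angular_rate"`.
#' @param l half-size (cm), constant-approach kind.
#' @param v approach speed (cm/s).
#' @param start_distance starting distance (cm).
#' @param angular_rate expansion rate (deg/s), constant-angular kind.
#' @param start_angle,end_angle ramp limits (deg).
#' @return list of class `StimulusProfile`: `time`, `theta_deg` (full
#'   angle), `l_over_v` (s), `l_over_v_ms`, `truncated`.
#' @export
loom_profile <- function(t, kind = c("constant_approach", "constant_angular_rate"),
                         l = 0.5, v = 62.5, start_distance = 50,
                         angular_rate = 500, start_angle = 0, end_angle = 30) {
  kind <- match.arg(kind)
  if (kind == "constant_approach") {
    stopifnot(l > 0, v > 0, start_distance > 0)
    tau <- (start_distance - v * t) / v
    theta <- ifelse(tau > 0, 2 * atan(l / (v * tau)) * 180 / pi, 180)
    truncated <- any(tau <= 0)
    structure(list(time = t, theta_deg = theta, l_over_v = l / v,
                   l_over_v_ms = 1000 * l / v, truncated = truncated),
              class = "StimulusProfile")
  } else {
    stopifnot(angular_rate > 0, end_angle > start_angle)
    theta <- pmin(start_angle + angular_rate * t, end_angle)
    structure(list(time = t, theta_deg = theta, l_over_v = NA_real_,
                   l_over_v_ms = NA_real_, truncated = FALSE),
              class = "StimulusProfile")
  }
}

#' Baseline-normalized fluorescence change (dF/F)
#'
#' `dF/F = (F_t - F0) / F0` with `F0` the mean fluorescence during the
#' `pre_window` seconds preceding stimulus onset.
#'
#' @param trace list with numeric `time` (s, strictly increasing),
#'   `F`, and `onset` (s).
#' @param pre_window baseline window length (s).
#' @return numeric vector of dF/F values, one per sample.
#' @export
dff <- function(trace, pre_window = 0.5) {
  stopifnot(all(diff(trace$time) > 0))
  base <- trace$time >= trace$onset - pre_window & trace$time < trace$onset
  if (!any(base)) stop("no pre-onset samples in the baseline window", call. = FALSE)
  f0 <- mean(trace$F[base])
  if (f0 <= 0) stop("baseline F0 must be > 0", call. = FALSE)
  (trace$F - f0) / f0
}

#' Directional tuning and directional sensitivity index (DSI)
#'
#' Computes the peak dF/F within the response window for each of the
#' 24 motion directions and the directional sensitivity index
#' `DSI = (R_up - R_down) / (R_up + R_down)`, where `R_up` is the peak
#' response to the upward-moving edge (0 deg) and `R_down` to the
#' downward-moving edge (180 deg). Negative peaks are floored at 0
#' before the index so it stays within `[-1, 1]`; when both cardinal
#' peaks are 0 the index is undefined (`NA`).
#'
#' @param traces list of 24 trace lists (fields `time`, `F`, `onset`,
#'   `direction`), one per direction 0..345 in 15-degree steps.
#' @param response_window seconds after onset in which to take the
#'   peak.
#' @param pre_window baseline window for [dff()].
#' @return list of class `TuningResult`: `directions`, `peaks`
#'   (floored peak dF/F per direction), `r_up`, `r_down`, `dsi`.
#' @export
directional_tuning <- function(traces, response_window = 2, pre_window = 0.5) {
  dirs <- vapply(traces, function(tr) tr$direction, numeric(1))
  if (length(traces) != 24 || !setequal(dirs, seq(0, 345, by = 15)))
    stop("exactly 24 traces covering 0..345 deg in 15-deg steps required",
         call. = FALSE)
  peaks <- vapply(traces, function(tr) {
    d <- dff(tr, pre_window)
    win <- tr$time >= tr$onset & tr$time <= tr$onset + response_window
    max(c(d[win], 0))  # floor negative responses at 0
  }, numeric(1))
  ord <- order(dirs)
  dirs <- dirs[ord]; peaks <- peaks[ord]
  r_up <- peaks[dirs == 0]
  r_down <- peaks[dirs == 180]
  dsi <- if (r_up + r_down > 0) (r_up - r_down) / (r_up + r_down) else NA_real_
  structure(list(directions = dirs, peaks = peaks, r_up = r_up,
                 r_down = r_down, dsi = dsi), class = "TuningResult")
}

#' Bootstrap mean with percentile confidence interval
#'
#' Seeded nonparametric bootstrap of the sample mean. The default
#' interval is the expanded percentile interval (a percentile interval
#' whose quantile levels carry a small-sample t-based adjustment),
#' which restores near-nominal coverage at small n; `expand = FALSE`
#' gives the plain 2.5/97.5 percentile interval.
#'
#' @param values numeric vector (n >= 2).
#' @param n_boot bootstrap replicates (default 10,000).
#' @param seed integer RNG seed.
#' @param conf confidence level.
#' @param expand use the small-sample level adjustment.
#' @return list with `mean`, `ci` (length 2), `n_boot`.
#' @export
bootstrap_mean <- function(values, n_boot = 10000, seed = 1L, conf = 0.95,
                           expand = TRUE) {
  n <- length(values)
  stopifnot(n >= 2)
  set.seed(seed)
  boots <- colMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                           nrow = n))
  alpha <- (1 - conf) / 2
  if (expand) alpha <- pnorm(-qt(1 - alpha, n - 1) * sqrt(n / (n - 1)))
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  list(mean = mean(values), ci = ci, n_boot = n_boot)
}

#' Gaussian-smoothed DSI heatmap with missing-cell handling
#'
#' Smooths a rectangular grid of DSI values with a Gaussian filter
#' (sigma in grid units, default 1). Missing cells are excluded via
#' normalized convolution: the smoothed value is the Gaussian-weighted
#' mean of valid neighbours, so the output stays within the input
#' range, and cells with no valid support remain `NA`.
#'
#' @param grid numeric matrix, `NA` for missing cells.
#' @param sigma Gaussian sigma in grid units.
#' @return smoothed matrix of the same shape.
#' @export
dsi_heatmap <- function(grid, sigma = 1) {
  stopifnot(is.matrix(grid))
  valid <- !is.na(grid)
  if (!any(valid)) stop("all cells missing", call. = FALSE)
  k <- gaussian_kernel_1d(sigma)
  h <- length(k) %/% 2
  vals <- grid
  vals[!valid] <- 0
  conv2 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    arr <- array(as.numeric(m), c(nr, nc, 1L))
    out <- conv3d_axis(as.numeric(arr), c(nr, nc, 1L), k, 0L)
    out <- conv3d_axis(out, c(nr, nc, 1L), k, 1L)
    matrix(out, nr, nc)
  }
  num <- conv2(vals)
  den <- conv2(valid * 1)
  out <- num / den
  out[den < 1e-12] <- NA
  out
}

#' Giant-fibre response summary from a membrane-potential trace
#'
#' The baseline is the mean membrane potential over the
#' `baseline_window` seconds before stimulus onset; the peak response
#' is the maximum baseline-subtracted potential within the
#' `response_window` after onset, and the area is the trapezoidal
#' integral of the baseline-subtracted potential over the same window
#' in ms x mV.
#'
#' @param trace list with `time` (s), `Vm` (mV).
#' @param onset stimulus onset (s).
#' @param baseline_window baseline length (s), default 2.
#' @param response_window response length (s), default 0.150.
#' @return list of class `EphysSummary`: `baseline`, `peak`,
#'   `area_ms_mv`.
#' @export
gf_response <- function(trace, onset, baseline_window = 2,
                        response_window = 0.150) {
  base <- trace$time >= onset - baseline_window & trace$time < onset
  win <- trace$time >= onset & trace$time <= onset + response_window
  if (!any(base) || !any(win))
    stop("baseline or response window outside trace bounds", call. = FALSE)
  b <- mean(trace$Vm[base])
  dv <- trace$Vm[win] - b
  tt <- trace$time[win] * 1000  # ms
  area <- if (length(dv) > 1) sum(diff(tt) * (head(dv, -1) + dv[-1]) / 2) else 0
  structure(list(baseline = b, peak = max(dv), area_ms_mv = area),
            class = "EphysSummary")
}
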