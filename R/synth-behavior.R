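#' Specification for synthetic looming-takeoff records
#'
#' Per stimulus elevation, each fly performs one takeoff whose mode is
#' Bernoulli(`p_short`); short-mode takeoff sequences last at most 7 ms
#' and long-mode sequences longer than 7 ms, matching the behavioural
#' classification boundary used downstream.
#'
#' @param elevations stimulus elevations in degrees.
#' @param n_per_elevation flies (one takeoff each) per elevation.
#' @param p_short probability of a short-mode takeoff at each
#'   elevation (recycled).
#' @param short_range uniform support (ms) for short durations, within
#'   (0, 7].
#' @param long_shape,long_scale gamma parameters for the long-mode
#'   duration excess over 7 ms.
#' @param seed integer RNG seed.
#' @return An object of class `SyntheticBehaviorSpec`.
#' @export
synthetic_behavior_spec <- function(elevations = c(-30, 0, 23, 45, 77),
                                    n_per_elevation = 100,
                                    p_short = c(0.2, 0.35, 0.5, 0.65, 0.8),
                                    short_range = c(2.5, 6.5),
                                    long_shape = 3, long_scale = 3,
                                    seed = 1L) {
  p_short <- rep_len(p_short, length(elevations))
  stopifnot(all(p_short >= 0 & p_short <= 1),
            short_range[1] > 0, short_range[2] <= 7,
            long_shape > 0, long_scale > 0)
  structure(list(elevations = elevations,
                 n_per_elevation = rep_len(as.integer(n_per_elevation),
                                           length(elevations)),
                 p_short = p_short, short_range = short_range,
                 long_shape = long_shape, long_scale = long_scale,
                 seed = as.integer(seed)),
            class = "SyntheticBehaviorSpec")
}

#' Generate synthetic takeoff records
#'
#' @param spec a [synthetic_behavior_spec()].
#' @return data frame with columns `fly_id`, `elevation`, `duration_ms`
#'   and `true_mode` ("short" or "long").
#' @export
gen_takeoffs <- function(spec) {
  stopifnot(inherits(spec, "SyntheticBehaviorSpec"))
  set.seed(spec$seed)
  out <- list()
  fly <- 0L
  for (e in seq_along(spec$elevations)) {
    n <- spec$n_per_elevation[e]
    short <- rbinom(n, 1, spec$p_short[e]) == 1
    dur <- numeric(n)
    dur[short] <- runif(sum(short), spec$short_range[1], spec$short_range[2])
    dur[!short] <- 7 + rgamma(sum(!short), spec$long_shape, scale = spec$long_scale)
    out[[e]] <- data.frame(
      fly_id = sprintf("fly_%04d", fly + seq_len(n)),
      elevation = spec$elevations[e], duration_ms = dur,
      true_mode = ifelse(short, "short", "long"), stringsAsFactors = FALSE)
    fly <- fly + n
  }
  do.call(rbind, out)
}
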