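#' Classify takeoff mode from takeoff-sequence duration
#'
#' Takeoff sequences lasting between 0 and 7 ms (inclusive) are
#' short-mode (the escape driven solely by giant-fibre activation);
#' durations longer than 7 ms are long-mode. When an outlier cutoff is
#' supplied (50 ms in the datasets where it applies), longer durations
#' are excluded.
#'
#' @param duration_ms numeric vector of takeoff-sequence durations
#'   (ms, > 0).
#' @param outlier_cutoff optional exclusion threshold (ms); `NULL`
#'   disables the rule.
#' @return character vector: `"short"`, `"long"` or `"excluded"`.
#' @export
classify_takeoff <- function(duration_ms, outlier_cutoff = NULL) {
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0))
    stop("durations must be finite and > 0", call. = FALSE)
  mode <- ifelse(duration_ms <= 7, "short", "long")
  if (!is.null(outlier_cutoff)) mode[duration_ms > outlier_cutoff] <- "excluded"
  mode
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- -qnorm((1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Short-mode takeoff percentage per elevation and elevation-gradient test
#'
#' Computes the short-mode takeoff percentage (short takeoffs / total
#' takeoffs) per stimulus elevation with Wilson 95% confidence
#' intervals, a chi-squared test of homogeneity over the
#' elevation-by-mode table, and Bonferroni-corrected pairwise
#' chi-squared comparisons.
#'
#' @param records data frame with columns `elevation` and either
#'   `mode` (from [classify_takeoff()]) or `duration_ms` (classified
#'   here); `"excluded"` takeoffs are dropped.
#' @param outlier_cutoff passed to [classify_takeoff()] when
#'   classifying from durations.
#' @return list with `percentages` (elevation, n, n_short,
#'   pct_short, ci_lo, ci_hi), `chisq` (htest), `p`, and `pairwise`
#'   (elevation_a, elevation_b, p_raw, p_bonferroni).
#' @export
shortmode_gradient <- function(records, outlier_cutoff = NULL) {
  if (is.null(records$mode))
    records$mode <- classify_takeoff(records$duration_ms, outlier_cutoff)
  records <- records[records$mode != "excluded", , drop = FALSE]
  counts <- table(records$elevation, records$mode == "short")
  elev <- as.numeric(rownames(counts))
  n <- rowSums(counts)
  if (any(n == 0)) {
    warning("dropping elevations with 0 takeoffs")
    counts <- counts[n > 0, , drop = FALSE]
    elev <- elev[n > 0]; n <- n[n > 0]
  }
  if (length(elev) < 2) stop("need >= 2 elevations with takeoffs", call. = FALSE)
  n_short <- if ("TRUE" %in% colnames(counts)) counts[, "TRUE"] else rep(0, length(n))
  ci <- t(vapply(seq_along(n), function(i) wilson_ci(n_short[i], n[i]),
                 numeric(2)))
  pct <- data.frame(elevation = elev, n = as.integer(n),
                    n_short = as.integer(n_short),
                    pct_short = 100 * n_short / n,
                    ci_lo = 100 * ci[, 1], ci_hi = 100 * ci[, 2])
  tab <- cbind(short = n_short, long = n - n_short)
  chisq <- suppressWarnings(chisq.test(tab))
  pairs <- utils::combn(seq_along(elev), 2)
  pw <- data.frame(
    elevation_a = elev[pairs[1, ]], elevation_b = elev[pairs[2, ]],
    p_raw = apply(pairs, 2, function(ij)
      suppressWarnings(chisq.test(tab[ij, , drop = FALSE]))$p.value))
  pw$p_bonferroni <- pmin(pw$p_raw * nrow(pw), 1)
  list(percentages = pct, chisq = chisq, p = chisq$p.value, pairwise = pw)
}

#' Rank-based comparison of duration distributions
#'
#' Two samples are compared with the Mann-Whitney U-test (exact when
#' both groups have at most `exact_max` observations and no ties,
#' normal approximation otherwise); more than two samples with the
#' Kruskal-Wallis test followed by Bonferroni-corrected pairwise
#' Mann-Whitney tests. Ties are handled by midranks.
#'
#' @param ... two or more numeric sample vectors, or a single list of
#'   them.
#' @param alternative passed to [stats::wilcox.test()] for the
#'   two-sample case.
#' @param exact_max largest per-group n for which the exact null
#'   distribution is used.
#' @return list with `statistic`, `p`, `method`, and (multi-sample)
#'   `pairwise` (group_a, group_b, p_raw, p_bonferroni).
#' @export
rank_tests <- function(..., alternative = "two.sided", exact_max = 8) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]])) samples <- samples[[1]]
  stopifnot(length(samples) >= 2, all(vapply(samples, length, 1L) >= 1))
  if (length(samples) == 2) {
    a <- samples[[1]]; b <- samples[[2]]
    use_exact <- max(length(a), length(b)) <= exact_max &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                       exact = use_exact))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "Mann-Whitney U")
  } else {
    kt <- kruskal.test(samples)
    pairs <- utils::combn(length(samples), 2)
    pw <- data.frame(
      group_a = pairs[1, ], group_b = pairs[2, ],
      p_raw = apply(pairs, 2, function(ij) {
        a <- samples[[ij[1]]]; b <- samples[[ij[2]]]
        use_exact <- max(length(a), length(b)) <= exact_max &&
          !anyDuplicated(c(a, b))
        suppressWarnings(wilcox.test(a, b, exact = use_exact))$p.value
      }))
    pw$p_bonferroni <- pmin(pw$p_raw * nrow(pw), 1)
    list(statistic = unname(kt$statistic), p = kt$p.value,
         method = "Kruskal-Wallis", pairwise = pw)
  }
}
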