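#' Per-neuron synapse totals with a named partner, max-normalized
#'
#' Sums synapse counts per neuron of the graded population and divides
#' by the maximum total, so the most strongly connected neuron scores
#' 1. The graded population may sit on either side of the connection
#' (`graded_side`): for a VPN-to-descending-neuron gradient the graded
#' neurons are the *sources*, whereas target-side grading sums each
#' target's inputs.
#'
#' @param adj adjacency data frame with columns `source_id`,
#'   `target_id`, `synapse_count`, `source_type`, `target_type`
#'   (unique source-target rows, counts >= 0).
#' @param graded_type type label of the graded population.
#' @param graded_side `"source"` or `"target"`.
#' @param partner_type optional type label restricting the partner
#'   side; `NULL` sums over all partners.
#' @param neurons optional ids of all graded neurons to report;
#'   neurons with no matching row get a total of 0. Defaults to the
#'   ids present in the selection.
#' @return data frame with columns `neuron_id`, `total`, `normalized`.
#' @export
total_synapses <- function(adj, graded_type, graded_side = c("source", "target"),
                           partner_type = NULL, neurons = NULL) {
  graded_side <- match.arg(graded_side)
  stopifnot(all(c("source_id", "target_id", "synapse_count",
                  "source_type", "target_type") %in% names(adj)))
  if (graded_side == "source") {
    sel <- adj$source_type == graded_type
    if (!is.null(partner_type)) sel <- sel & adj$target_type == partner_type
    ids <- adj$source_id
  } else {
    sel <- adj$target_type == graded_type
    if (!is.null(partner_type)) sel <- sel & adj$source_type == partner_type
    ids <- adj$target_id
  }
  if (!any(sel))
    stop("no adjacency rows match graded_type='", graded_type,
         "' on the ", graded_side, " side",
         if (!is.null(partner_type)) paste0(" with partner_type='",
                                            partner_type, "'"),
         call. = FALSE)
  sub <- data.frame(id = ids[sel], count = adj$synapse_count[sel])
  tot <- tapply(sub$count, sub$id, sum)
  if (is.null(neurons)) neurons <- sort(names(tot))
  totals <- as.numeric(tot[as.character(neurons)])
  totals[is.na(totals)] <- 0
  mx <- max(totals)
  data.frame(neuron_id = as.character(neurons), total = totals,
             normalized = if (mx > 0) totals / mx else totals,
             stringsAsFactors = FALSE)
}

#' Linear regression of synapse totals on the dorsoventral axis
#'
#' Ordinary least squares of per-neuron synapse totals against the
#' normalized dorsoventral position (0 = ventral, 1 = dorsal), with a
#' 95% confidence interval on the slope.
#'
#' @param totals data frame from [total_synapses()] (columns
#'   `neuron_id`, `total`).
#' @param positions data frame with columns `neuron_id`,
#'   `dv_position`; neurons are matched by id and unmatched ids are
#'   reported in the result.
#' @param value which totals column to regress (`"total"` or
#'   `"normalized"`).
#' @return list of class `GradientFit` with `slope`, `slope_ci`,
#'   `intercept`, `r_squared`, `p`, `n`, `residuals`, `unmatched`,
#'   and the underlying `lm` fit.
#' @export
dv_regression <- function(totals, positions, value = "total") {
  m <- merge(totals, positions, by = "neuron_id")
  unmatched <- setdiff(totals$neuron_id, positions$neuron_id)
  if (nrow(m) < 3) stop("need >= 3 matched neurons", call. = FALSE)
  if (sd(m$dv_position) == 0) stop("all positions equal", call. = FALSE)
  fit <- lm(m[[value]] ~ m$dv_position)
  ci <- unname(confint(fit, level = 0.95)[2, ])
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]), slope_ci = ci,
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4], n = nrow(m),
                 residuals = unname(fit$residuals), unmatched = unmatched,
                 fit = fit), class = "GradientFit")
}

#' Antiparallel synaptic-gradient check for two source types
#'
#' Fits [dv_regression()] for two graded populations against the same
#' position table and flags a genuine antiparallel pair: both slope
#' CIs exclude zero, with opposite signs.
#'
#' @param adj adjacency table (see [total_synapses()]).
#' @param type_a,type_b the two graded type labels.
#' @param positions neuron position table.
#' @param graded_side,partner_type passed to [total_synapses()].
#' @return list with `fit_a`, `fit_b`, `opposite_sign`.
#' @export
antiparallel_check <- function(adj, type_a, type_b, positions,
                               graded_side = "source", partner_type = NULL) {
  fa <- dv_regression(total_synapses(adj, type_a, graded_side, partner_type),
                      positions)
  fb <- dv_regression(total_synapses(adj, type_b, graded_side, partner_type),
                      positions)
  excl <- function(f) f$slope_ci[1] > 0 || f$slope_ci[2] < 0
  flag <- excl(fa) && excl(fb) && sign(fa$slope) != sign(fb$slope)
  list(fit_a = fa, fit_b = fb, opposite_sign = flag)
}

#' Map normalized synapse totals to colours for visualization export
#'
#' Linear map of normalized totals onto a declared colour scale,
#' emitting one hex colour per neuron (the export used to colour-code
#' connectome reconstructions by synapse count).
#'
#' @param totals data frame from [total_synapses()].
#' @param palette colour scale name passed to [grDevices::hcl.colors()].
#' @param n_steps resolution of the scale.
#' @return data frame with columns `neuron_id`, `value`, `colour`.
#' @export
colormap_export <- function(totals, palette = "Viridis", n_steps = 256) {
  cols <- hcl.colors(n_steps, palette)
  idx <- pmin(pmax(floor(totals$normalized * (n_steps - 1)) + 1, 1), n_steps)
  data.frame(neuron_id = totals$neuron_id, value = totals$normalized,
             colour = cols[idx], stringsAsFactors = FALSE)
}
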