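#' Specification for a synthetic connectome adjacency table
#'
#' One postsynaptic target neuron receives synapses from `n_source`
#' graded source neurons whose expected synapse count is
#' `slope * dv_position + intercept` (clipped at 0), with Poisson or
#' negative-binomial count noise. An optional antiparallel second
#' source type shares the same positions with an opposite-signed slope.
#'
#' @param n_source number of source neurons.
#' @param slope expected synapses per unit dorsoventral position.
#' @param intercept expected synapses at the ventral end.
#' @param noise `"poisson"` or `"nb"`.
#' @param nb_dispersion NB overdispersion when `noise = "nb"`.
#' @param antiparallel_pair if `TRUE`, a second source type with slope
#'   `-slope` and intercept `intercept + slope` (same expected count at
#'   the opposite end) is generated on the same positions.
#' @param source_types labels for the one or two source types.
#' @param seed integer RNG seed.
#' @return An object of class `SyntheticConnectomeSpec`.
#' @export
synthetic_connectome_spec <- function(n_source = 100, slope = 20, intercept = 2,
                                      noise = c("poisson", "nb"),
                                      nb_dispersion = 5,
                                      antiparallel_pair = FALSE,
                                      source_types = c("typeA", "typeB"),
                                      seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_source >= 1, nb_dispersion > 0)
  mu_ends <- c(intercept, slope + intercept)
  if (all(mu_ends < 0))
    stop("expected counts negative over the whole position range", call. = FALSE)
  structure(list(n_source = as.integer(n_source), slope = slope,
                 intercept = intercept, noise = noise,
                 nb_dispersion = nb_dispersion,
                 antiparallel_pair = isTRUE(antiparallel_pair),
                 source_types = source_types, seed = as.integer(seed)),
            class = "SyntheticConnectomeSpec")
}

#' Generate a synthetic adjacency table with a linear DV synapse gradient
#'
#' @param spec a [synthetic_connectome_spec()].
#' @return list with `adjacency` (source_id, target_id, synapse_count,
#'   source_type, target_type), `positions` (neuron_id, dv_position)
#'   and `truth` (per-type slope and intercept).
#' @export
gen_connectome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticConnectomeSpec"))
  set.seed(spec$seed)
  n <- spec$n_source
  pos <- runif(n)
  draw <- function(mu) {
    mu <- pmax(mu, 0)
    if (spec$noise == "poisson") rpois(n, mu)
    else rnbinom(n, mu = mu, size = spec$nb_dispersion)
  }
  types <- spec$source_types[1]
  slopes <- spec$slope
  intercepts <- spec$intercept
  if (spec$antiparallel_pair) {
    types <- spec$source_types[1:2]
    slopes <- c(spec$slope, -spec$slope)
    intercepts <- c(spec$intercept, spec$intercept + spec$slope)
  }
  adj <- list()
  positions <- list()
  for (t in seq_along(types)) {
    ids <- sprintf("%s_%03d", types[t], seq_len(n))
    counts <- draw(slopes[t] * pos + intercepts[t])
    adj[[t]] <- data.frame(source_id = ids, target_id = "target_1",
                           synapse_count = counts, source_type = types[t],
                           target_type = "target", stringsAsFactors = FALSE)
    positions[[t]] <- data.frame(neuron_id = ids, dv_position = pos,
                                 stringsAsFactors = FALSE)
  }
  list(adjacency = do.call(rbind, adj),
       positions = do.call(rbind, positions),
       truth = data.frame(source_type = types, slope = slopes,
                          intercept = intercepts, stringsAsFactors = FALSE))
}
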