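#' Sampler configuration
#'
#' Parameters of iterative native-biased sampling. E_min is the energy of the
#' open (fully extended) chain and E_max defaults to twice E_min; together
#' they define the linear acceptance ramp.
#'
#' @param E_min open-chain energy, kJ/mol.
#' @param E_max upper acceptance bound, kJ/mol (default \code{2 * E_min}).
#' @param target_count number of accepted conformations to aim for (>= 1).
#' @param max_attempts cap on perturbation proposals.
#' @param perturb_magnitude maximum per-torsion displacement, degrees.
#' @param perturb_count number of torsions perturbed per proposal.
#' @param flex_weight sampling weight of a flexible torsion unit relative to
#'   a rigid one when drawing perturbation indices (default 4).
#' @param rng_seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return An object of class \code{"sampler_config"}.
#' @export
sampler_config <- function(E_min, E_max = 2 * E_min, target_count = 50L,
                           max_attempts = 50L * target_count,
                           perturb_magnitude = 30, perturb_count = NULL,
                           flex_weight = 4, rng_seed = NULL) {
  stopifnot(E_max > E_min, target_count >= 1L, perturb_magnitude > 0,
            flex_weight > 0)
  structure(list(E_min = E_min, E_max = E_max,
                 target_count = as.integer(target_count),
                 max_attempts = as.integer(max_attempts),
                 perturb_magnitude = perturb_magnitude,
                 perturb_count = perturb_count,
                 flex_weight = flex_weight, rng_seed = rng_seed),
            class = "sampler_config")
}

#' Energy-ramp acceptance probability
#'
#' 1 below E_min (including the E_min boundary, by continuity from below), a
#' linear ramp from 1 to 0 on (E_min, E_max], and 0 above E_max.
#'
#' @param E_q conformation energy, kJ/mol (vectorized; \code{Inf} gives 0).
#' @param cfg a \code{\link{sampler_config}} (only E_min/E_max are used).
#' @return acceptance probability in [0, 1].
#' @export
#' @examples
#' cfg <- sampler_config(E_min = 100, target_count = 1)
#' acceptance_probability(c(50, 150, 250), cfg)
acceptance_probability <- function(E_q, cfg) {
  p <- (cfg$E_max - E_q) / (cfg$E_max - cfg$E_min)
  p[E_q <= cfg$E_min] <- 1
  p[E_q > cfg$E_max] <- 0
  p
}

#' Generate conformations by iterative native-biased perturbation
#'
#' Grows a tree of samples rooted at the native state: a parent is drawn
#' uniformly from the accepted set, a set of torsions is drawn with rigidity
#' bias (torsions outside rigid clusters of the parent's rigidity map carry
#' \code{flex_weight} times the weight of rigid ones; terminal placeholder
#' torsions are never perturbed), the proposal's energy decides acceptance by
#' a Bernoulli draw with \code{\link{acceptance_probability}}. Every accepted
#' conformation carries its cached sampling-phase energy, so every returned
#' conformation has energy at most E_max.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param model an \code{\link{energy_model}}.
#' @param cfg a \code{\link{sampler_config}}.
#' @param pool optional list of previously accepted conformations used as
#'   perturbation parents (the native state when \code{NULL}); the sampling
#'   tree then continues from them.
#' @param id_start integer from which new sample ids (\code{s0001}, ...) are
#'   numbered.
#' @param include_native prepend the native conformation (id
#'   \code{"native"}) to the returned set.
#' @return list of \code{\link{conformation}} objects with cached energies.
#' @export
generate_samples <- function(topo, model, cfg, pool = NULL, id_start = 1L,
                             include_native = TRUE) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  native <- conformation(topo$native_torsions, id = "native")
  native$energy <- total_energy(topo, native, model, phase = "sampling")
  if (!is.finite(native$energy)) stop("native conformation is infeasible")
  if (is.null(pool)) pool <- list(native)
  flex <- flexible_torsion_indices(topo)
  npert <- cfg$perturb_count
  if (is.null(npert)) npert <- max(1L, round(0.1 * 2L * topo$n))
  npert <- min(npert, length(flex))
  accepted <- list()
  attempts <- 0L
  proposals_in_band <- 0L
  nid <- id_start
  # the native root counts toward the target when it is part of the output
  needed <- cfg$target_count - as.integer(include_native)
  while (length(accepted) < needed &&
         attempts < cfg$max_attempts) {
    attempts <- attempts + 1L
    parent <- pool[[sample.int(length(pool), 1L)]]
    rmap <- rigid_cluster_decomposition(topo, parent, model)
    sizes <- tabulate(unclass(rmap))
    rigid_unit <- sizes[unclass(rmap)] > 1L
    w <- ifelse(rigid_unit[flex], 1, cfg$flex_weight)
    if (all(w == w[1L])) w <- rep(1, length(flex))  # degenerate: uniform
    idx <- sample(flex, npert, prob = w)
    q <- perturb(parent, idx, cfg$perturb_magnitude,
                 id = sprintf("s%04d", nid))
    E <- total_energy(topo, q, model, phase = "sampling")
    pacc <- acceptance_probability(E, cfg)
    if (is.finite(E) && E > cfg$E_min) proposals_in_band <- proposals_in_band + 1L
    if (stats::runif(1L) < pacc) {
      q$energy <- E
      accepted[[length(accepted) + 1L]] <- q
      pool[[length(pool) + 1L]] <- q
      nid <- nid + 1L
    }
  }
  if (length(accepted) == 0L && needed > 0L && attempts >= cfg$max_attempts)
    stop(sprintf(paste0("no proposal accepted in %d attempts ",
                        "(%d proposals above E_min); consider a larger ",
                        "perturbation magnitude or attempt budget"),
                 attempts, proposals_in_band))
  if (include_native) c(list(native), accepted) else accepted
}
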