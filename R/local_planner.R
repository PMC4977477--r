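#' Straight-line torsional interpolation
#'
#' Uniform interpolation between two conformations along the minimal angular
#' path of every torsion, with the number of steps set by the largest
#' per-torsion span: \code{m = ceiling(max span / resolution)} (and m = 1
#' when the endpoints coincide). Every per-torsion step is at most
#' \code{resolution} degrees.
#'
#' @param a,b \code{\link{conformation}} objects or torsion vectors.
#' @param resolution maximum per-torsion step in degrees (> 0).
#' @return an (m + 1) x 2n matrix of torsion vectors; the first row is a, the
#'   last is b.
#' @export
interpolate_conformations <- function(a, b, resolution = 5) {
  stopifnot(resolution > 0)
  ta <- if (inherits(a, "conformation")) a$torsions else a
  tb <- if (inherits(b, "conformation")) b$torsions else b
  stopifnot(length(ta) == length(tb))
  delta <- normalize_angle(tb - ta)
  m <- max(1L, ceiling(max(abs(delta)) / resolution))
  steps <- seq(0, 1, length.out = m + 1L)
  out <- t(vapply(steps, function(s) normalize_angle(ta + s * delta),
                  numeric(length(ta))))
  out[m + 1L, ] <- normalize_angle(tb)  # land exactly on b
  out
}

#' Boltzmann transition probability between consecutive intermediates
#'
#' \code{exp(-dE / kT)} for an uphill step (dE > 0), 1 for a downhill or flat
#' step; an infinite dE (infeasible intermediate) gives 0.
#'
#' @param dE energy difference E(next) - E(current), kJ/mol.
#' @param kT thermal energy in the same units.
#' @return probability in [0, 1]. Vectorized over \code{dE}.
#' @export
transition_probability <- function(dE, kT = 1) {
  p <- ifelse(dE <= 0, 1, exp(-dE / kT))
  p[is.infinite(dE) & dE > 0] <- 0
  # NaN arises from Inf - Inf energy differences; treat as infeasible
  p[is.nan(dE)] <- 0
  p
}

# Directional edge weights from the energy profile along a path:
# sum of -log P_i over consecutive pairs, in the forward and reverse
# traversal directions.
path_weights <- function(E, kT = 1) {
  dE <- diff(E)
  fw <- -log(transition_probability(dE, kT))
  rv <- -log(transition_probability(-dE, kT))
  list(forward = sum(fw), reverse = sum(rv))
}

#' Attempt a connection between two conformations
#'
#' Evaluates the straight-line intermediates (connecting-phase clash
#' threshold) and, when all are feasible, the directional edge weights
#' \code{sum(-log P_i)} for the forward (a to b) and reverse traversals.
#' Endpoint energies are taken from the conformations' caches when set, so
#' cached energies are not recounted; every fresh evaluation increments the
#' model's energy-call counter, which is the attempt's cost.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param a,b feasible \code{\link{conformation}} objects.
#' @param model an \code{\link{energy_model}}.
#' @param resolution interpolation resolution in degrees.
#' @return list with \code{success}, \code{forward_weight},
#'   \code{reverse_weight} (both finite iff success), \code{energy_calls}
#'   incurred by this attempt, and \code{intermediates} (interior count).
#' @export
connect_pair <- function(topo, a, b, model = energy_model(), resolution = 5) {
  calls0 <- energy_calls(model)
  path <- interpolate_conformations(a, b, resolution)
  m <- nrow(path)
  E <- numeric(m)
  E[1L] <- if (!is.na(a$energy)) a$energy else
    total_energy(topo, path[1L, ], model, phase = "connecting")
  E[m] <- if (!is.na(b$energy)) b$energy else
    total_energy(topo, path[m, ], model, phase = "connecting")
  ok <- is.finite(E[1L]) && is.finite(E[m])
  if (ok && m > 2L) for (i in 2L:(m - 1L)) {
    E[i] <- total_energy(topo, path[i, ], model, phase = "connecting")
    if (!is.finite(E[i])) { ok <- FALSE; break }
  }
  if (!ok)
    return(list(success = FALSE, forward_weight = Inf, reverse_weight = Inf,
                energy_calls = energy_calls(model) - calls0,
                intermediates = m - 2L))
  w <- path_weights(E, model$kT)
  list(success = TRUE, forward_weight = w$forward, reverse_weight = w$reverse,
       energy_calls = energy_calls(model) - calls0, intermediates = m - 2L)
}
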