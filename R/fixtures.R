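# Synthetic fixtures: toy proteins with declared native secondary structure,
# and mock connection environments for exercising the learners without real
# planners. Everything is deterministic under R's seeded RNG.

# Ramachandran ideals used for native segment torsions.
.IDEAL_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                        strand = c(phi = -119, psi = 113))

#' Generate a toy protein with declared native structure
#'
#' Builds a small chain whose native torsions are the standard Ramachandran
#' ideals inside each declared segment (helix phi/psi -57/-47, strand
#' -119/113) and seeded-random elsewhere; loop torsions are re-drawn until
#' the native conformation is clash-free. The default sequence alternates a
#' hydrophobic valine every third residue against serine.
#'
#' @param n residue count (4..40).
#' @param plan \code{"helix"} (one helix spanning the chain) or
#'   \code{"two-helix"} (two helices separated by a 2-residue loop), or a
#'   segments data frame as in \code{\link{protein_topology}}.
#' @param sequence optional explicit residue codes (length n).
#' @param seed integer seed for the loop torsion draws.
#' @param max_tries resampling budget for a clash-free native.
#' @param pdb_path when non-NULL, the native structure is also written there
#'   as a PDB file (see \code{\link{write_native_pdb}}).
#' @return A \code{\link{protein_topology}}.
#' @export
#' @examples
#' topo <- make_toy_protein(8, plan = "helix", seed = 1)
#' topo$segments
make_toy_protein <- function(n = 8L, plan = "helix", sequence = NULL,
                             seed = 1L, max_tries = 1000L, pdb_path = NULL) {
  stopifnot(n >= 4L, n <= 40L)
  if (is.character(plan)) {
    plan <- match.arg(plan, c("helix", "two-helix"))
    segments <- if (plan == "helix") {
      data.frame(label = "H1", kind = "helix", start = 0L, end = n)
    } else {
      h1 <- max(5L, (n - 2L) %/% 2L)
      if (n - h1 - 2L < 5L) stop("chain too short for two helices")
      data.frame(label = c("H1", "H2"), kind = "helix",
                 start = c(0L, h1 + 2L), end = c(h1, n))
    }
  } else segments <- plan
  if (is.null(sequence))
    sequence <- ifelse(seq_len(n) %% 3L == 1L, "VAL", "SER")
  in_seg <- rep(FALSE, n)
  tors <- rep(180, 2L * n)
  for (s in seq_len(nrow(segments))) {
    rs <- (segments$start[s] + 1L):segments$end[s]
    in_seg[rs] <- TRUE
    ideal <- .IDEAL_TORSIONS[[segments$kind[s]]]
    tors[2L * rs - 1L] <- ideal[["phi"]]
    tors[2L * rs] <- ideal[["psi"]]
  }
  tors[c(1L, 2L * n)] <- 180  # undefined terminal dihedrals
  loop_res <- which(!in_seg)
  loop_idx <- setdiff(c(2L * loop_res - 1L, 2L * loop_res), c(1L, 2L * n))
  set.seed(seed)
  model <- energy_model()
  topo <- NULL
  for (try in seq_len(max_tries)) {
    if (length(loop_idx))
      tors[loop_idx] <- stats::runif(length(loop_idx), -180, 180)
    cand <- protein_topology(sequence, tors, segments = segments)
    xyz <- forward_kinematics(cand, cand$native_torsions)
    if (clash_check(cand, xyz, model, "sampling")) { topo <- cand; break }
    if (!length(loop_idx)) break
  }
  if (is.null(topo))
    stop("could not generate a clash-free native in ", max_tries, " tries")
  if (!is.null(pdb_path)) write_native_pdb(topo, pdb_path)
  topo
}

#' Mock two-region connection environment
#'
#' A synthetic landscape for studying method locality: queries fall in one
#' of two regions of torsion space (separated centers, so torsional distance
#' identifies the region) and two mock connection methods have mirrored
#' success probabilities — method A succeeds at \code{p_favored} in region 1
#' and \code{p_other} in region 2, method B the reverse. Region 1 is drawn
#' more often (default 70/30), making A the globally dominant method even
#' though it is the wrong choice inside region 2. Successful attempts yield
#' an edge weight uniform in \code{y_range} and every attempt costs one
#' energy call. Plugs into the learners in place of real planners.
#'
#' @param p_favored,p_other success probability of the locally favored /
#'   disfavored method (defaults 0.9 / 0.1).
#' @param region_prob sampling probabilities of the two regions.
#' @param n_torsions torsion dimension of the mock conformations.
#' @param y_range range of edge weights granted on success.
#' @return An object of class \code{"two_region_bench"} with elements
#'   \code{methods}, \code{favored} (method favored per region),
#'   \code{sample_query()} and \code{attempt(region, method)} — both
#'   consuming R's global RNG stream.
#' @export
make_two_region_bench <- function(p_favored = 0.9, p_other = 0.1,
                                  region_prob = c(0.7, 0.3),
                                  n_torsions = 8L, y_range = c(1, 2)) {
  stopifnot(length(region_prob) == 2L, all(region_prob >= 0))
  region_prob <- region_prob / sum(region_prob)
  centers <- rbind(rep(-90, n_torsions), rep(90, n_torsions))
  favored <- c("A", "B")
  p_success <- rbind(c(p_favored, p_other),   # region 1: A favored
                     c(p_other, p_favored))   # region 2: B favored
  colnames(p_success) <- c("A", "B")
  bench <- list(
    methods = c("A", "B"),
    favored = favored,
    n_torsions = n_torsions,
    region_prob = region_prob,
    sample_query = function() {
      region <- sample.int(2L, 1L, prob = region_prob)
      tors <- normalize_angle(centers[region, ] +
                                stats::runif(n_torsions, -20, 20))
      list(region = region, tors = tors)
    },
    attempt = function(region, method) {
      ok <- stats::runif(1L) < p_success[region, method]
      list(success = ok,
           y = if (ok) stats::runif(1L, y_range[1L], y_range[2L]) else Inf,
           cost = 1)
    })
  class(bench) <- "two_region_bench"
  bench
}

#' Run a learner on a mock connection environment
#'
#' Drives ANC-local (per-query neighbourhood replay) or ANC-global (one
#' persistent bandit state) for a number of steps on a
#' \code{\link{make_two_region_bench}} environment, recording for every step
#' the region, the method selected, and whether it was the locally favored
#' one.
#'
#' @param bench a \code{"two_region_bench"}.
#' @param algorithm \code{"anc-local"} or \code{"anc-global"}.
#' @param steps number of queries.
#' @param gamma,alpha bandit constants.
#' @param nf_local local learning region size (ANC-local).
#' @param seed integer seed.
#' @return data frame with columns \code{step}, \code{region},
#'   \code{method}, \code{correct}.
#' @export
run_bench <- function(bench, algorithm = c("anc-local", "anc-global"),
                      steps = 300L, gamma = 0.1, alpha = 0.5,
                      nf_local = 40L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  set.seed(seed)
  log <- attempt_log(bench$n_torsions)
  state <- bandit_state(bench$methods, gamma, alpha)
  region <- integer(steps)
  method <- character(steps)
  for (t in seq_len(steps)) {
    q <- bench$sample_query()
    p <- if (algorithm == "anc-local")
      anc_local_probabilities(q$tors, log, bench$methods, gamma, alpha,
                              nf_local)
    else cost_adjusted_probability(state)
    mid <- sample_method(p)
    out <- bench$attempt(q$region, mid)
    if (algorithm == "anc-global")
      state <- bandit_observe(state, mid, out$success, out$y, out$cost)$state
    log_append(log, node = sprintf("q%05d", t), tors = q$tors, method = mid,
               success = out$success, y = out$y, cost = out$cost)
    region[t] <- q$region
    method[t] <- mid
  }
  data.frame(step = seq_len(steps), region = region, method = method,
             correct = method == bench$favored[region],
             stringsAsFactors = FALSE)
}
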