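#' Coarse-grained energy model
#'
#' Parameters of the Go-like coarse potential: every constraint (backbone bond
#' or native hydrogen bond) of current length d contributes
#' \code{K_d * (sqrt((d - d_0)^2 + d_c^2) - d_c)} kJ/mol, and hydrophobic
#' residue pairs in contact contribute a step-function term. Conformations
#' with non-bonded atoms closer than a phase-dependent threshold (2.4 A while
#' sampling, 1.0 A while connecting) are infeasible and get energy +Inf.
#'
#' The model also owns the potential-energy call counter: every call to
#' \code{\link{total_energy}} increments it, and the counter is the cost
#' currency of the connection-method bandit.
#'
#' @param K_d constraint force scale, kJ/mol (default 100).
#' @param d_0 constraint rest length, Angstrom (default 2).
#' @param d_c constraint softening length, Angstrom (default 2).
#' @param clash_sampling,clash_connect minimum allowed non-bonded atom
#'   distance in the sampling and connecting phases (2.4 / 1.0 A).
#' @param hp_cutoff CB-CB distance cutoff for a hydrophobic contact (6 A).
#' @param hp_energy energy per hydrophobic contact, kJ/mol (<= 0, default -1).
#' @param kT thermal energy in reduced units for transition probabilities
#'   (default 1).
#' @return An object of class \code{"energy_model"}.
#' @export
energy_model <- function(K_d = 100, d_0 = 2, d_c = 2,
                         clash_sampling = 2.4, clash_connect = 1.0,
                         hp_cutoff = 6, hp_energy = -1, kT = 1) {
  stopifnot(K_d > 0, d_c > 0, clash_connect < clash_sampling,
            hp_energy <= 0, kT > 0)
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  env$precomp <- list()
  structure(list(K_d = K_d, d_0 = d_0, d_c = d_c,
                 clash_sampling = clash_sampling,
                 clash_connect = clash_connect,
                 hp_cutoff = hp_cutoff, hp_energy = hp_energy,
                 kT = kT, env = env),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("Energy model: K_d=%g d_0=%g d_c=%g kJ/mol|A, ",
                     "clash %g/%g A, hp (%g A, %g kJ/mol), kT=%g\n",
                     "  energy calls so far: %d\n"),
              x$K_d, x$d_0, x$d_c, x$clash_sampling, x$clash_connect,
              x$hp_cutoff, x$hp_energy, x$kT, x$env$calls))
  invisible(x)
}

#' Energy-call counter
#'
#' @param model an \code{\link{energy_model}}.
#' @return \code{energy_calls}: the number of \code{\link{total_energy}}
#'   invocations since creation or the last reset.
#' @export
energy_calls <- function(model) model$env$calls

#' @rdname energy_calls
#' @export
reset_energy_calls <- function(model) {
  model$env$calls <- 0L
  invisible(model)
}

# Per-topology precomputation: covalent bonds, clash exclusion mask, and the
# constraint set. Cached in the model's environment, keyed by a cheap
# topology fingerprint.
.energy_precomp <- function(topo, model) {
  key <- paste0(topo$n, ":", paste(topo$sequence, collapse = ""), ":",
                format(sum(topo$native_torsions), digits = 12))
  pc <- model$env$precomp[[key]]
  if (!is.null(pc)) return(pc)
  n <- topo$n
  na <- 6L * n
  idx <- function(i, a) (i - 1L) * 6L + a  # a: 1N 2H 3CA 4CB 5C 6O
  bonds <- list()
  for (i in seq_len(n)) {
    bonds[[length(bonds) + 1L]] <- rbind(
      c(idx(i, 1L), idx(i, 2L)),   # N-H
      c(idx(i, 1L), idx(i, 3L)),   # N-CA
      c(idx(i, 3L), idx(i, 4L)),   # CA-CB
      c(idx(i, 3L), idx(i, 5L)),   # CA-C
      c(idx(i, 5L), idx(i, 6L)))   # C-O
    if (i < n)
      bonds[[length(bonds) + 1L]] <- rbind(c(idx(i, 5L), idx(i + 1L, 1L)))
  }
  bonds <- do.call(rbind, bonds)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  bd <- igraph::distances(g)
  excl <- bd <= 3                       # within 3 covalent bonds
  at <- rep(.ATOM_NAMES, n)
  ho <- outer(at == "H", at == "O", "&")
  excl <- excl | ho | t(ho)             # amide H / carbonyl O: hydrogen bonds
  diag(excl) <- TRUE

  # constraints: backbone chain bonds + native hydrogen bonds (O..N <= 3.5 A,
  # |i-j| >= 3, both residues inside native segments)
  ci <- cj <- integer(0); role <- character(0)
  ri <- rj <- integer(0)
  for (i in seq_len(n)) {
    ci <- c(ci, idx(i, 1L), idx(i, 3L)); cj <- c(cj, idx(i, 3L), idx(i, 5L))
    ri <- c(ri, i, i); rj <- c(rj, i, i)
    role <- c(role, "backbone", "backbone")
    if (i < n) {
      ci <- c(ci, idx(i, 5L)); cj <- c(cj, idx(i + 1L, 1L))
      ri <- c(ri, i); rj <- c(rj, i + 1L)
      role <- c(role, "backbone")
    }
  }
  seg <- topo$segments
  in_seg <- rep(FALSE, n)
  if (nrow(seg)) for (s in seq_len(nrow(seg)))
    in_seg[(seg$start[s] + 1L):seg$end[s]] <- TRUE
  nat <- forward_kinematics(topo, topo$native_torsions)
  if (any(in_seg)) {
    for (i in seq_len(n)) {
      if (!in_seg[i]) next
      for (j in seq_len(n)) {
        if (!in_seg[j] || abs(i - j) < 3L) next
        d <- sqrt(sum((nat[idx(i, 6L), ] - nat[idx(j, 1L), ])^2))
        if (d <= 3.5) {
          ci <- c(ci, idx(i, 6L)); cj <- c(cj, idx(j, 1L))
          ri <- c(ri, i); rj <- c(rj, j)
          role <- c(role, "hbond")
        }
      }
    }
  }
  dnat <- sqrt(rowSums((nat[ci, , drop = FALSE] - nat[cj, , drop = FALSE])^2))
  pc <- list(excl = excl,
             constraints = data.frame(i = ci, j = cj, role = role,
                                      res_i = ri, res_j = rj,
                                      d_native = dnat),
             cb_idx = idx(seq_len(n), 4L),
             hydro = topo$hydrophobic)
  model$env$precomp[[key]] <- pc
  pc
}

#' The constraint set of a topology
#'
#' Backbone chain bonds (N-CA, CA-C, C-N) plus native hydrogen-bond pairs
#' detected on the native structure (carbonyl O to amide N within 3.5 A,
#' sequence separation >= 3, both residues inside native segments). The
#' current lengths of these atom pairs are the d_i of the constraint term.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param model an \code{\link{energy_model}}.
#' @return data frame with atom indices \code{i}, \code{j}, \code{role}
#'   (\code{"backbone"}/\code{"hbond"}), residue indices and native length.
#' @export
constraint_set <- function(topo, model = energy_model()) {
  .energy_precomp(topo, model)$constraints
}

#' Steric feasibility check
#'
#' A conformation is feasible when every non-exempt atom pair is at least the
#' phase threshold apart (2.4 A in the sampling phase, 1.0 A in the connecting
#' phase). Exempt pairs are those within 3 covalent bonds and amide-H /
#' carbonyl-O pairs (hydrogen-bond partners, which legitimately approach
#' ~2 A).
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param coords a \code{\link{forward_kinematics}} coordinate set.
#' @param model an \code{\link{energy_model}}.
#' @param phase \code{"sampling"} or \code{"connecting"}.
#' @return \code{TRUE} if feasible.
#' @export
clash_check <- function(topo, coords, model = energy_model(),
                        phase = c("sampling", "connecting")) {
  phase <- match.arg(phase)
  thr <- if (phase == "sampling") model$clash_sampling else model$clash_connect
  pc <- .energy_precomp(topo, model)
  d <- as.matrix(stats::dist(coords))
  ut <- upper.tri(d)
  all(d[ut & !pc$excl] >= thr)
}

#' Hydrophobic interaction term
#'
#' Step-function contact potential: each pair of hydrophobic residues with
#' sequence separation >= 3 whose CB atoms lie within the cutoff contributes
#' \code{hp_energy} (<= 0) kJ/mol.
#'
#' @inheritParams clash_check
#' @return E_hp in kJ/mol.
#' @export
hydrophobic_term <- function(topo, coords, model = energy_model()) {
  hy <- which(topo$hydrophobic)
  if (length(hy) < 2L) return(0)
  pc <- .energy_precomp(topo, model)
  cb <- coords[pc$cb_idx[hy], , drop = FALSE]
  d <- as.matrix(stats::dist(cb))
  sep <- abs(outer(hy, hy, "-"))
  cnt <- sum(d[upper.tri(d)] <= model$hp_cutoff & sep[upper.tri(sep)] >= 3L)
  cnt * model$hp_energy
}

#' Total potential energy of a conformation
#'
#' Increments the model's energy-call counter, realizes the conformation (or
#' uses supplied coordinates), applies the phase clash check, and if feasible
#' returns the constraint term summed over the constraint set plus the
#' hydrophobic term; infeasible conformations get \code{Inf}.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param conf a \code{\link{conformation}} or bare torsion vector.
#' @param model an \code{\link{energy_model}}.
#' @param phase clash-check phase, \code{"sampling"} or \code{"connecting"}.
#' @param coords optional precomputed coordinate set for \code{conf}.
#' @return energy in kJ/mol, or \code{Inf} when infeasible.
#' @export
total_energy <- function(topo, conf, model = energy_model(),
                         phase = c("sampling", "connecting"), coords = NULL) {
  phase <- match.arg(phase)
  model$env$calls <- model$env$calls + 1L
  if (is.null(coords)) coords <- forward_kinematics(topo, conf)
  if (!clash_check(topo, coords, model, phase)) return(Inf)
  pc <- .energy_precomp(topo, model)
  cs <- pc$constraints
  d <- sqrt(rowSums((coords[cs$i, , drop = FALSE] -
                       coords[cs$j, , drop = FALSE])^2))
  u <- sum(model$K_d * (sqrt((d - model$d_0)^2 + model$d_c^2) - model$d_c))
  u + hydrophobic_term(topo, coords, model)
}

#' Energy of the open (fully extended) chain
#'
#' The conformation with every flexible torsion at 180 degrees; its energy
#' defines E_min of the sampling acceptance ramp.
#'
#' @inheritParams total_energy
#' @return energy in kJ/mol.
#' @export
open_chain_energy <- function(topo, model = energy_model()) {
  e <- total_energy(topo, rep(180, 2L * topo$n), model, phase = "sampling")
  if (!is.finite(e))
    stop(paste0("the fully extended chain clashes; choose a different ",
                "E_min convention for this topology"))
  e
}
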