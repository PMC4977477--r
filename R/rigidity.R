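#' Rigid-cluster decomposition of a conformation
#'
#' A simplified rigid-cluster analysis over the 2n torsion units (residue
#' major: phi_1, psi_1, phi_2, ...). Clusters are the connected components of
#' the graph whose edges join units coupled by a currently satisfied
#' constraint: each native hydrogen bond whose current length is within 110%
#' of its native length couples the phi/psi units of both residues, and
#' consecutive residues inside the same native segment are chained together
#' when both participate in a satisfied hydrogen bond. The result is a
#' partition of the torsion units; its same-cluster indicator is the rigidity
#' map consumed by the cluster distance metric and by rigidity-biased
#' perturbation. The interface admits a drop-in exact pebble-game
#' decomposition later.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param conf a \code{\link{conformation}} or bare torsion vector.
#' @param model an \code{\link{energy_model}}.
#' @param coords optional precomputed coordinates for \code{conf}.
#' @return An object of class \code{"rigidity_map"}: an integer
#'   cluster-membership vector over the 2n torsion units (cluster ids
#'   canonicalized by first occurrence).
#' @export
rigid_cluster_decomposition <- function(topo, conf, model = energy_model(),
                                        coords = NULL) {
  n <- topo$n
  if (is.null(coords)) coords <- forward_kinematics(topo, conf)
  cs <- .energy_precomp(topo, model)$constraints
  hb <- cs[cs$role == "hbond", , drop = FALSE]
  edges <- NULL
  involved <- rep(FALSE, n)
  if (nrow(hb)) {
    d <- sqrt(rowSums((coords[hb$i, , drop = FALSE] -
                         coords[hb$j, , drop = FALSE])^2))
    sat <- d <= 1.1 * hb$d_native
    if (any(sat)) {
      ri <- hb$res_i[sat]; rj <- hb$res_j[sat]
      involved[unique(c(ri, rj))] <- TRUE
      u <- function(r, a) 2L * (r - 1L) + a  # a: 1 phi, 2 psi (1-based unit)
      edges <- rbind(cbind(u(ri, 1L), u(ri, 2L)),
                     cbind(u(rj, 1L), u(rj, 2L)),
                     cbind(u(ri, 1L), u(rj, 1L)))
      seg <- topo$segments
      if (nrow(seg)) for (s in seq_len(nrow(seg))) {
        rs <- (seg$start[s] + 1L):seg$end[s]
        if (length(rs) > 1L) for (r in rs[-length(rs)])
          if (involved[r] && involved[r + 1L])
            edges <- rbind(edges, c(u(r, 2L), u(r + 1L, 1L)))
      }
    }
  }
  g <- igraph::make_empty_graph(n = 2L * n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # canonical labels: clusters numbered by first occurrence
  memb <- match(memb, unique(memb))
  structure(as.integer(memb), class = "rigidity_map", n_units = 2L * n)
}

#' @export
print.rigidity_map <- function(x, ...) {
  k <- length(unique(unclass(x)))
  cat(sprintf("Rigidity map: %d torsion units in %d clusters\n",
              length(x), k))
  invisible(x)
}

#' Rigidity distance between two conformations' maps
#'
#' The number of unordered torsion-unit pairs on which the two same-cluster
#' indicators disagree (pairs rigidly coupled in one conformation but not the
#' other). A pseudometric on rigidity maps. Computed in O(2n) from the
#' cluster contingency table rather than by enumerating pairs.
#'
#' @param a_map,b_map \code{"rigidity_map"} objects over the same 2n units.
#' @return nonnegative integer count, at most \code{choose(2n, 2)}.
#' @export
rigidity_distance <- function(a_map, b_map) {
  a <- unclass(a_map); b <- unclass(b_map)
  if (length(a) != length(b))
    stop("rigidity maps are over different index domains")
  pairs2 <- function(x) sum(choose(tabulate(x), 2))
  tab <- table(a, b)
  same_both <- sum(choose(tab, 2))
  pairs2(a) + pairs2(b) - 2 * same_both
}
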