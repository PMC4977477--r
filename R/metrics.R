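#' Torsional Euclidean distance between conformations
#'
#' Root-mean-square difference over the 2n phi/psi angles, with each
#' difference taken on the circle (minimal signed angular difference, so 179
#' vs -179 degrees counts as 2 degrees). Returned in degrees.
#'
#' @param a,b \code{\link{conformation}} objects or bare torsion vectors of
#'   equal length 2n.
#' @return nonnegative distance in degrees.
#' @export
#' @examples
#' euclidean_distance(c(0, 0, 0, 0), c(2, 0, 0, 0))
euclidean_distance <- function(a, b) {
  ta <- if (inherits(a, "conformation")) a$torsions else a
  tb <- if (inherits(b, "conformation")) b$torsions else b
  if (length(ta) != length(tb))
    stop("conformations have different torsion counts")
  d <- normalize_angle(ta - tb)
  sqrt(sum(d^2) / length(d))
}

#' Root mean square distance between coordinate sets
#'
#' Plain (non-superposed) RMSD over the 6n atoms using the full 3-D
#' displacement of each atom.
#'
#' @param x,y 6n x 3 coordinate matrices with identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(x, y) {
  if (!all(dim(x) == dim(y)))
    stop("coordinate sets have different dimensions")
  sqrt(sum((x - y)^2) / nrow(x))
}

#' Least RMSD under rigid-body superposition
#'
#' Minimum RMSD over all rigid-body superpositions of the two coordinate
#' sets: both are centered and the optimal rotation is found by the Kabsch
#' algorithm (SVD of the cross-covariance, with the proper-rotation sign
#' fix). Always at most \code{\link{rmsd}(x, y)}. Degenerate inputs (all
#' atoms coincident) fall back to RMSD after centroid alignment.
#'
#' @inheritParams rmsd
#' @return least RMSD in Angstrom.
#' @export
lrmsd <- function(x, y) {
  if (!all(dim(x) == dim(y)))
    stop("coordinate sets have different dimensions")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  h <- crossprod(xc, yc)
  s <- tryCatch(svd(h), error = function(e) NULL)
  if (is.null(s) || all(s$d < 1e-12)) return(rmsd(xc, yc))
  sgn <- sign(det(s$v %*% t(s$u)))
  if (sgn == 0) sgn <- 1
  r <- s$v %*% diag(c(1, 1, sgn)) %*% t(s$u)
  rmsd(xc %*% t(r), yc)
}

#' Metric evaluation context
#'
#' Caches per-conformation derived objects (coordinates, rigidity maps) keyed
#' by conformation id, so that the cluster and lRMSD metrics do not recompute
#' them for every pairwise evaluation.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param model an \code{\link{energy_model}}.
#' @return An environment-backed object of class \code{"metric_context"}.
#' @export
metric_context <- function(topo, model = energy_model()) {
  env <- new.env(parent = emptyenv())
  env$coords <- new.env(parent = emptyenv())
  env$rig <- new.env(parent = emptyenv())
  structure(list(topo = topo, model = model, env = env),
            class = "metric_context")
}

context_coords <- function(ctx, conf) {
  got <- ctx$env$coords[[conf$id]]
  if (!is.null(got)) return(got)
  xyz <- forward_kinematics(ctx$topo, conf)
  ctx$env$coords[[conf$id]] <- xyz
  xyz
}

context_rigidity <- function(ctx, conf) {
  got <- ctx$env$rig[[conf$id]]
  if (!is.null(got)) return(got)
  rm_ <- rigid_cluster_decomposition(ctx$topo, conf, ctx$model,
                                     coords = context_coords(ctx, conf))
  ctx$env$rig[[conf$id]] <- rm_
  rm_
}

#' Conformation distance metric by name
#'
#' Returns the callable metric used by neighbor selection:
#' \code{"euclidean"} (torsional RMS, degrees), \code{"cluster"} (rigidity
#' distance between cached rigidity maps), or \code{"lrmsd"} (least RMSD of
#' cached coordinates, Angstrom). All are symmetric, nonnegative, and zero on
#' identical conformations.
#'
#' @param name one of \code{"euclidean"}, \code{"cluster"}, \code{"lrmsd"}.
#' @param ctx a \code{\link{metric_context}} (required for \code{cluster} and
#'   \code{lrmsd}).
#' @return function of two conformations returning a nonnegative real.
#' @export
distance_metric <- function(name = c("euclidean", "cluster", "lrmsd"),
                            ctx = NULL) {
  name <- match.arg(name)
  if (name == "euclidean") return(euclidean_distance)
  if (is.null(ctx)) stop("metric '", name, "' needs a metric_context")
  if (name == "cluster")
    return(function(a, b)
      rigidity_distance(context_rigidity(ctx, a), context_rigidity(ctx, b)))
  function(a, b) lrmsd(context_coords(ctx, a), context_coords(ctx, b))
}

#' Exact k-closest neighbor selection
#'
#' Brute-force neighbor search: evaluates the metric against every candidate
#' and returns the k smallest (all, if fewer exist), ascending, with ties
#' broken deterministically by conformation id. The query is excluded from
#' its own candidates by id.
#'
#' @param q query \code{\link{conformation}}.
#' @param candidates list of candidate conformations.
#' @param k number of neighbors (>= 1).
#' @param metric function of two conformations, as from
#'   \code{\link{distance_metric}}.
#' @return data frame with columns \code{id} and \code{distance}, at most k
#'   rows, ascending by (distance, id).
#' @export
k_closest <- function(q, candidates, k, metric = euclidean_distance) {
  stopifnot(k >= 1L)
  sc <- .score_candidates(q, candidates, metric)
  if (nrow(sc) == 0L) return(sc)
  utils::head(sc, k)
}

#' Radius neighbor selection
#'
#' All candidates within metric distance r of the query (query excluded by
#' id), ascending by (distance, id).
#'
#' @inheritParams k_closest
#' @param r nonnegative radius.
#' @return data frame with columns \code{id} and \code{distance}.
#' @export
r_closest <- function(q, candidates, r, metric = euclidean_distance) {
  stopifnot(r >= 0)
  sc <- .score_candidates(q, candidates, metric)
  sc[sc$distance <= r, , drop = FALSE]
}

.score_candidates <- function(q, candidates, metric) {
  ids <- vapply(candidates, function(cc) cc$id, character(1L))
  keep <- ids != q$id
  ids <- ids[keep]
  candidates <- candidates[keep]
  d <- vapply(candidates, function(cc) metric(q, cc), numeric(1L))
  out <- data.frame(id = ids, distance = d, stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
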