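# Roadmap assembly and analysis: an env-backed builder grown by the
# connection operators, finalized into a plain list for analysis and
# serialization.

#' Create an empty roadmap builder
#'
#' A mutable (environment-backed) weighted directed graph over conformations.
#' Nodes are conformations with cached energies; each directed edge carries
#' the traversal weight sum(-log P_i), the id of the connection method that
#' produced it, and the attempt step. The builder also owns the shared
#' metric context and the attempt log.
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param model an \code{\link{energy_model}}.
#' @param k neighbors attempted per connection query (default 20).
#' @param resolution local-planner interpolation resolution, degrees.
#' @return An object of class \code{"roadmap"}.
#' @export
roadmap <- function(topo, model = energy_model(), k = 20L, resolution = 5) {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$ids <- character(0)
  e$edges <- list()
  e$ctx <- metric_context(topo, model)
  e$log <- attempt_log(2L * topo$n)
  structure(list(env = e, topo = topo, model = model, k = as.integer(k),
                 resolution = resolution),
            class = "roadmap")
}

#' @export
print.roadmap <- function(x, ...) {
  cat(sprintf("Roadmap: %d nodes, %d directed edges, %d attempts logged\n",
              length(x$env$nodes), length(x$env$edges), log_size(x$env$log)))
  invisible(x)
}

#' Add a conformation to a roadmap
#'
#' @param rm a \code{\link{roadmap}}.
#' @param conf a \code{\link{conformation}} with a cached finite energy and
#'   an id unique within the roadmap.
#' @return the roadmap, invisibly.
#' @export
add_node <- function(rm, conf) {
  e <- rm$env
  if (conf$id %in% e$ids) stop("duplicate node id: ", conf$id)
  e$nodes[[conf$id]] <- conf
  e$ids <- c(e$ids, conf$id)
  invisible(rm)
}

# The candidate connection methods: k-closest under each distance metric,
# sharing the roadmap's cached metric context.
.roadmap_metric <- function(rm, method_id) {
  distance_metric(method_id, rm$env$ctx)
}

# Attempt connections from q to its k nearest prior nodes under the given
# method; adds directed edges for successes and logs every attempt.
# Returns the per-attempt outcomes.
.connect_with_method <- function(rm, q, method_id) {
  e <- rm$env
  others <- e$nodes[setdiff(e$ids, q$id)]
  out <- list()
  if (length(others)) {
    nbrs <- k_closest(q, others, rm$k, .roadmap_metric(rm, method_id))
    for (i in seq_len(nrow(nbrs))) {
      nb <- e$nodes[[nbrs$id[i]]]
      res <- connect_pair(rm$topo, q, nb, rm$model, rm$resolution)
      step <- log_size(e$log) + 1L
      if (res$success) {
        e$edges[[length(e$edges) + 1L]] <-
          list(from = q$id, to = nb$id, weight = res$forward_weight,
               method = method_id, step = step)
        e$edges[[length(e$edges) + 1L]] <-
          list(from = nb$id, to = q$id, weight = res$reverse_weight,
               method = method_id, step = step)
      }
      log_append(e$log, node = q$id, tors = q$torsions, method = method_id,
                 success = res$success, y = res$forward_weight,
                 cost = res$energy_calls)
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

#' Connect a node with a fixed connection method
#'
#' @param rm a \code{\link{roadmap}} already containing \code{q}.
#' @param q the query \code{\link{conformation}}.
#' @param method_id \code{"euclidean"}, \code{"cluster"} or \code{"lrmsd"}.
#' @return the roadmap, invisibly.
#' @export
connect_node_fixed <- function(rm, q, method_id) {
  .connect_with_method(rm, q, method_id)
  invisible(rm)
}

#' Connect a node with locally learned method selection
#'
#' The ANC-local step: replays the \code{nf_local} logged attempts nearest
#' to q (torsional Euclidean distance) through a fresh bandit state
#' (\code{\link{anc_local_probabilities}}), samples a connection method from
#' the resulting cost-adjusted probabilities, attempts q's k nearest
#' neighbors under it, and appends one attempt record per attempt. With an
#' empty history the selection is uniform.
#'
#' @inheritParams connect_node_fixed
#' @param methods candidate method ids.
#' @param gamma,alpha bandit constants.
#' @param nf_local local learning region size.
#' @return the selected method id, invisibly.
#' @export
connect_node_local <- function(rm, q, methods = c("euclidean", "cluster",
                                                  "lrmsd"),
                               gamma = 0.1, alpha = 0.5, nf_local = 40L) {
  p <- anc_local_probabilities(q$torsions, rm$env$log, methods,
                               gamma, alpha, nf_local)
  mid <- sample_method(p)
  .connect_with_method(rm, q, mid)
  invisible(mid)
}

#' Connect a node with globally learned method selection
#'
#' The ANC-global step: one persistent bandit state shared across all nodes;
#' the method is sampled from its cost-adjusted probabilities and every
#' attempt outcome is folded back into the state.
#'
#' @inheritParams connect_node_local
#' @param state the persistent \code{\link{bandit_state}}.
#' @return list with the updated \code{state} and the selected \code{method}.
#' @export
connect_node_global <- function(rm, q, state) {
  p <- cost_adjusted_probability(state)
  mid <- sample_method(p)
  outs <- .connect_with_method(rm, q, mid)
  for (res in outs)
    state <- bandit_observe(state, mid, res$success, res$forward_weight,
                            res$energy_calls)$state
  list(state = state, method = mid)
}

#' Edge table of a roadmap
#'
#' @param rm a \code{\link{roadmap}}.
#' @return data frame with columns \code{from}, \code{to}, \code{weight},
#'   \code{method}, \code{step}.
#' @export
roadmap_edges <- function(rm) {
  e <- rm$env$edges
  if (!length(e))
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), method = character(),
                      step = integer(), stringsAsFactors = FALSE))
  data.frame(from = vapply(e, `[[`, "", "from"),
             to = vapply(e, `[[`, "", "to"),
             weight = vapply(e, `[[`, 0, "weight"),
             method = vapply(e, `[[`, "", "method"),
             step = vapply(e, function(x) as.integer(x$step), 0L),
             stringsAsFactors = FALSE)
}

#' @rdname roadmap_edges
#' @return \code{node_energies}: named vector of cached node energies.
#' @export
node_energies <- function(rm) {
  vapply(rm$env$nodes, function(cc) cc$energy, numeric(1L))
}

#' Identify the unfolded states of a roadmap
#'
#' The denatured ensemble is not observed directly; here it is
#' operationalized as the nodes in the top decile of potential energy among
#' roadmap nodes (configurable quantile, native excluded, minimum one node).
#'
#' @param rm a \code{\link{roadmap}}.
#' @param quantile lower bound quantile of the energy distribution
#'   (default 0.9: the top decile).
#' @return character vector of node ids.
#' @export
unfolded_states <- function(rm, quantile = 0.9) {
  en <- node_energies(rm)
  en <- en[names(en) != "native"]
  if (!length(en)) return(character(0))
  thr <- stats::quantile(en, quantile, names = FALSE, type = 7)
  ids <- names(en)[en >= thr]
  if (!length(ids)) ids <- names(en)[which.max(en)]
  sort(ids)
}

#' Extract folding pathways from a roadmap
#'
#' For every unfolded state, the minimum-total-weight directed path to the
#' native state (Dijkstra on the -log transition probability weights, so the
#' result is the maximum-probability folding path). Unreachable unfolded
#' states are skipped with a notice.
#'
#' @param rm a \code{\link{roadmap}} whose nodes include \code{"native"}.
#' @param quantile passed to \code{\link{unfolded_states}}.
#' @return list of pathways, each a character vector of node ids ordered
#'   from the unfolded state to native, with attribute \code{"weight"}.
#' @export
extract_folding_pathways <- function(rm, quantile = 0.9) {
  ed <- roadmap_edges(rm)
  ids <- rm$env$ids
  if (!("native" %in% ids)) stop("roadmap has no native node")
  g <- igraph::graph_from_data_frame(
    ed[, c("from", "to", "weight")], directed = TRUE,
    vertices = data.frame(name = sort(ids)))
  starts <- unfolded_states(rm, quantile)
  paths <- list()
  for (s in starts) {
    if (s == "native") next
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = s, to = "native",
                             weights = igraph::E(g)$weight,
                             output = "both"))
    vp <- sp$vpath[[1L]]
    if (length(vp) == 0L) {
      message("unfolded state ", s, " cannot reach native; skipped")
      next
    }
    w <- sum(igraph::E(g)$weight[as.integer(sp$epath[[1L]])])
    p <- igraph::as_ids(vp)
    attr(p, "weight") <- w
    paths[[length(paths) + 1L]] <- p
  }
  paths
}

# Per-segment native hydrogen-bond constraint indices (a constraint belongs
# to every segment that contains one of its residues).
.segment_hbonds <- function(topo, model) {
  cs <- .energy_precomp(topo, model)$constraints
  hb <- cs[cs$role == "hbond", , drop = FALSE]
  seg <- topo$segments
  lapply(seq_len(nrow(seg)), function(s) {
    rs <- (seg$start[s] + 1L):seg$end[s]
    which(hb$res_i %in% rs | hb$res_j %in% rs)
  })
}

#' Secondary-structure formation order along a pathway
#'
#' Walks a pathway from the unfolded state to native and records, for each
#' native segment, the first conformation at which at least 70 percent of
#' the segment's native hydrogen bonds are satisfied (within 110 percent of
#' their native length). Segments are returned in order of that formation
#' point; ties and never-formed segments fall back to native (N- to
#' C-terminal) order, never-formed ones last.
#'
#' @param rm a \code{\link{roadmap}}.
#' @param path character vector of node ids, unfolded first.
#' @param formed_fraction fraction of a segment's native hydrogen bonds that
#'   must be satisfied (default 0.7).
#' @return character vector of segment labels in formation order.
#' @export
ssfo_of_path <- function(rm, path, formed_fraction = 0.7) {
  topo <- rm$topo
  seg <- topo$segments
  if (!nrow(seg)) stop("topology has no native segments")
  cs <- .energy_precomp(topo, rm$model)$constraints
  hb <- cs[cs$role == "hbond", , drop = FALSE]
  seg_idx <- .segment_hbonds(topo, rm$model)
  formed_at <- rep(Inf, nrow(seg))
  for (k in seq_along(path)) {
    conf <- rm$env$nodes[[path[k]]]
    xyz <- context_coords(rm$env$ctx, conf)
    d <- sqrt(rowSums((xyz[hb$i, , drop = FALSE] -
                         xyz[hb$j, , drop = FALSE])^2))
    sat <- d <= 1.1 * hb$d_native
    for (s in seq_len(nrow(seg))) {
      if (is.finite(formed_at[s])) next
      idx <- seg_idx[[s]]
      if (length(idx) && mean(sat[idx]) >= formed_fraction)
        formed_at[s] <- k
    }
    if (all(is.finite(formed_at))) break
  }
  seg$label[order(formed_at, seq_len(nrow(seg)))]
}

#' Distribution of formation orders across pathways
#'
#' @param rm a \code{\link{roadmap}}.
#' @param pathways as from \code{\link{extract_folding_pathways}}.
#' @param formed_fraction see \code{\link{ssfo_of_path}}.
#' @return An object of class \code{"ssfo_distribution"}: data frame with
#'   columns \code{order} (labels joined by \code{">"}) and \code{pct},
#'   summing to 100; attribute \code{"n_pathways"}.
#' @export
ssfo_distribution <- function(rm, pathways, formed_fraction = 0.7) {
  if (!length(pathways)) {
    out <- data.frame(order = character(), pct = numeric())
  } else {
    ords <- vapply(pathways, function(p)
      paste(ssfo_of_path(rm, p, formed_fraction), collapse = ">"),
      character(1L))
    tab <- table(ords)
    out <- data.frame(order = names(tab),
                      pct = 100 * as.numeric(tab) / length(ords),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$pct, out$order), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_pathways") <- length(pathways)
  class(out) <- c("ssfo_distribution", class(out))
  out
}

#' Maximum per-ordering change between two formation-order distributions
#'
#' Orderings absent from one distribution count at 0 percent. The roadmap is
#' declared stable when this change is at most the stability threshold
#' (30 points by default elsewhere) — a change of exactly the threshold
#' still counts as stable.
#'
#' @param d1,d2 \code{\link{ssfo_distribution}} objects.
#' @return largest absolute percentage-point change of any ordering.
#' @export
ssfo_change <- function(d1, d2) {
  orders <- union(d1$order, d2$order)
  if (!length(orders)) return(0)
  p1 <- stats::setNames(rep(0, length(orders)), orders)
  p2 <- p1
  p1[d1$order] <- d1$pct
  p2[d2$order] <- d2$pct
  max(abs(p1 - p2))
}

#' Dominant formation order
#'
#' The ordering with the greatest percentage of pathways; ties are broken
#' lexicographically with a warning.
#'
#' @param dist an \code{\link{ssfo_distribution}} with at least one pathway.
#' @return the dominant ordering string (labels joined by \code{">"}).
#' @export
dominant_order <- function(dist) {
  if (!nrow(dist)) stop("empty formation-order distribution")
  top <- dist[dist$pct == max(dist$pct), , drop = FALSE]
  if (nrow(top) > 1L)
    warning("tied dominant orderings; choosing lexicographically first")
  sort(top$order)[1L]
}

#' Compare a dominant order against an experimental ordering
#'
#' Case-insensitive exact tuple match of the ordering strings.
#'
#' @param dist an \code{\link{ssfo_distribution}}.
#' @param experimental ordering string, labels joined by \code{">"} (or a
#'   comma-separated string).
#' @return \code{TRUE} when the dominant order agrees.
#' @export
validate_order <- function(dist, experimental) {
  exp_ord <- gsub(",", ">", gsub("\\s", "", experimental))
  tolower(dominant_order(dist)) == tolower(exp_ord)
}

#' Folding pathway quality
#'
#' Sum over roadmap edges of (edge weight) x (number of extracted pathways
#' traversing the edge). Edges on no pathway contribute nothing; lower
#' values indicate cheaper, more heavily shared folding routes.
#'
#' @param rm a \code{\link{roadmap}}.
#' @param pathways as from \code{\link{extract_folding_pathways}}.
#' @return nonnegative total.
#' @export
pathway_quality <- function(rm, pathways) {
  if (!length(pathways)) return(0)
  ed <- roadmap_edges(rm)
  if (!nrow(ed)) return(0)
  key <- paste(ed$from, ed$to, sep = "\r")
  dominance <- stats::setNames(rep(0, nrow(ed)), key)
  for (p in pathways) {
    if (length(p) < 2L) next
    pk <- paste(p[-length(p)], p[-1L], sep = "\r")
    hit <- pk[pk %in% key]
    for (h in hit) dominance[[h]] <- dominance[[h]] + 1
  }
  sum(ed$weight * dominance[key])
}

#' Per-method usage, success and cost report
#'
#' Summarizes the attempt log: per connection method the share of attempts
#' (usage percentage), the local-planner success rate (connections made out
#' of connections attempted), and the cumulative energy-call cost.
#'
#' @param log_df attempt log as a data frame (see
#'   \code{\link{attempt_log}}), or a \code{\link{roadmap}}.
#' @return An object of class \code{"method_report"}: data frame with one
#'   row per method plus attributes \code{"total_attempts"} and
#'   \code{"total_cost"}.
#' @export
method_report <- function(log_df) {
  if (inherits(log_df, "roadmap")) log_df <- as.data.frame(log_df$env$log)
  stopifnot(is.data.frame(log_df))
  if (!nrow(log_df)) {
    out <- data.frame(method = character(), attempts = integer(),
                      successes = integer(), success_rate = numeric(),
                      usage_pct = numeric(), total_cost = numeric())
  } else {
    methods <- sort(unique(log_df$method))
    out <- do.call(rbind, lapply(methods, function(mid) {
      sub <- log_df[log_df$method == mid, , drop = FALSE]
      data.frame(method = mid, attempts = nrow(sub),
                 successes = sum(sub$success),
                 success_rate = mean(sub$success),
                 usage_pct = 100 * nrow(sub) / nrow(log_df),
                 total_cost = sum(sub$cost),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  attr(out, "total_attempts") <- nrow(log_df)
  attr(out, "total_cost") <- sum(log_df$cost)
  class(out) <- c("method_report", class(out))
  out
}
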