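#' Build a folding-landscape roadmap model
#'
#' The package's central fitting function. Starting from the native state it
#' alternates batches of native-biased sampling and neighbor connection,
#' extracts minimum-weight folding pathways from the unfolded states to
#' native after every batch, and stops when the distribution of
#' secondary-structure formation orders along those pathways stabilizes
#' (no ordering's percentage moves by more than \code{stability_threshold}
#' points between successive batches; a change of exactly the threshold
#' still counts as stable).
#'
#' The connection phase is driven by \code{strategy}: a fixed single-metric
#' connection method (\code{"euclidean"}, \code{"cluster"}, \code{"lrmsd"},
#' each meaning k-closest neighbor selection under that metric plus the
#' straight-line local planner), or adaptive selection among all three by an
#' Exp3-style bandit — \code{"anc-global"} with one run-wide state,
#' \code{"anc-local"} with per-query replay of the nearest recorded attempts
#' (see \code{\link{anc_local_probabilities}}).
#'
#' @param topo a \code{\link{protein_topology}}.
#' @param strategy connection strategy (see Details).
#' @param model an \code{\link{energy_model}}.
#' @param batch conformations sampled per construction batch.
#' @param max_batches hard cap on batches; reaching it without stabilizing
#'   flags the fit as non-converged.
#' @param k neighbors attempted per connection query (default 20).
#' @param nf_local local learning region size for \code{"anc-local"}
#'   (default 40).
#' @param gamma,alpha bandit constants (see \code{\link{bandit_state}}).
#' @param resolution local-planner resolution, degrees.
#' @param perturb_magnitude sampler perturbation magnitude, degrees.
#' @param stability_threshold stopping threshold in percentage points
#'   (default 30).
#' @param unfolded_quantile energy quantile defining the unfolded ensemble
#'   (default 0.9).
#' @param seed integer seed; the whole build is reproducible under it.
#' @return An object of class \code{"prm_fold"} with the roadmap, the
#'   attempt log, the extracted pathways, the formation-order distribution
#'   and the per-method report. Inspect with \code{print}, \code{summary}
#'   and \code{plot}.
#' @export
#' @examples
#' \donttest{
#' topo <- make_toy_protein(8, plan = "helix", seed = 1)
#' fit <- prm_fold(topo, strategy = "euclidean", batch = 10,
#'                 max_batches = 3, k = 5, seed = 1)
#' print(fit)
#' }
prm_fold <- function(topo,
                     strategy = c("anc-local", "anc-global", "euclidean",
                                  "cluster", "lrmsd"),
                     model = energy_model(), batch = 20L, max_batches = 8L,
                     k = 20L, nf_local = 40L, gamma = 0.1, alpha = 0.5,
                     resolution = 5, perturb_magnitude = 30,
                     stability_threshold = 30, unfolded_quantile = 0.9,
                     seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(topo, "protein_topology"), batch >= 1L,
            max_batches >= 1L)
  set.seed(seed)
  methods <- c("cluster", "euclidean", "lrmsd")
  E_min <- open_chain_energy(topo, model)
  cfg <- sampler_config(E_min, target_count = batch + 1L,
                        perturb_magnitude = perturb_magnitude)
  rm_ <- roadmap(topo, model, k = k, resolution = resolution)
  state <- bandit_state(methods, gamma, alpha)
  n_sampled <- 0L
  prev_dist <- NULL
  stable <- FALSE
  pathways <- list()
  dist <- NULL
  batches <- 0L
  for (b in seq_len(max_batches)) {
    batches <- b
    pool <- if (b == 1L) NULL else unname(rm_$env$nodes)
    new <- generate_samples(topo, model, cfg, pool = pool,
                            id_start = n_sampled + 1L,
                            include_native = b == 1L)
    n_sampled <- n_sampled + length(new) - as.integer(b == 1L)
    for (q in new) {
      add_node(rm_, q)
      if (length(rm_$env$ids) == 1L) next
      if (strategy == "anc-local") {
        connect_node_local(rm_, q, methods, gamma, alpha, nf_local)
      } else if (strategy == "anc-global") {
        state <- connect_node_global(rm_, q, state)$state
      } else {
        connect_node_fixed(rm_, q, strategy)
      }
    }
    pathways <- extract_folding_pathways(rm_, unfolded_quantile)
    dist <- ssfo_distribution(rm_, pathways)
    if (!is.null(prev_dist) && length(pathways) >= 1L &&
        ssfo_change(prev_dist, dist) <= stability_threshold) {
      stable <- TRUE
      break
    }
    prev_dist <- dist
  }
  if (!length(pathways))
    stop(sprintf(paste0("no unfolded-to-native pathway after %d batches ",
                        "(%d nodes, %d edges); the roadmap is too sparse — ",
                        "increase batch size or the attempt budget"),
                 batches, length(rm_$env$ids), length(rm_$env$edges)))
  fit <- list(topo = topo, strategy = strategy, model = model,
              roadmap = rm_, edges = roadmap_edges(rm_),
              log = as.data.frame(rm_$env$log),
              pathways = pathways, ssfo = dist,
              quality = pathway_quality(rm_, pathways),
              report = method_report(as.data.frame(rm_$env$log)),
              batches = batches, stable = stable,
              params = list(batch = batch, max_batches = max_batches, k = k,
                            nf_local = nf_local, gamma = gamma,
                            alpha = alpha, resolution = resolution,
                            perturb_magnitude = perturb_magnitude,
                            stability_threshold = stability_threshold,
                            unfolded_quantile = unfolded_quantile,
                            E_min = E_min, E_max = cfg$E_max),
              seed = seed)
  class(fit) <- "prm_fold"
  fit
}

#' @export
print.prm_fold <- function(x, ...) {
  cat(sprintf("Folding roadmap (strategy: %s)\n", x$strategy))
  cat(sprintf("  %d nodes, %d directed edges, %d attempts, %d batch(es)%s\n",
              length(x$roadmap$env$ids), nrow(x$edges), nrow(x$log),
              x$batches,
              if (x$stable) ", stable" else ", NOT converged"))
  cat(sprintf("  %d folding pathway(s); pathway quality %.4g\n",
              length(x$pathways), x$quality))
  if (nrow(x$ssfo))
    cat(sprintf("  dominant formation order: %s (%.1f%% of pathways)\n",
                dominant_order(x$ssfo), max(x$ssfo$pct)))
  invisible(x)
}

#' @export
summary.prm_fold <- function(object, ...) {
  print(object)
  en <- node_energies(object$roadmap)
  cat(sprintf("  node energy: min %.4g, median %.4g, max %.4g kJ/mol\n",
              min(en), stats::median(en), max(en)))
  cat(sprintf("  E_min (open chain) %.4g, E_max %.4g kJ/mol\n",
              object$params$E_min, object$params$E_max))
  cat("\nPer-method report:\n")
  print(as.data.frame(object$report), digits = 3)
  if (nrow(object$ssfo)) {
    cat("\nFormation-order distribution:\n")
    print(as.data.frame(object$ssfo), digits = 3)
  }
  invisible(object)
}

#' Plot a fitted folding roadmap
#'
#' Two base-graphics panels: connection-method usage with local-planner
#' success rates, and the energy profile along the best (lowest-weight)
#' folding pathway.
#'
#' @param x a \code{\link{prm_fold}} object.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
plot.prm_fold <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rep_ <- x$report
  if (nrow(rep_)) {
    graphics::barplot(rep_$usage_pct, names.arg = rep_$method,
                      ylab = "usage (% of attempts)", main = x$strategy,
                      col = "steelblue")
  }
  if (length(x$pathways)) {
    w <- vapply(x$pathways, function(p) attr(p, "weight"), numeric(1L))
    best <- x$pathways[[which.min(w)]]
    en <- vapply(best, function(id) x$roadmap$env$nodes[[id]]$energy,
                 numeric(1L))
    graphics::plot(seq_along(en), en, type = "b", pch = 16,
                   xlab = "pathway step (unfolded to native)",
                   ylab = "energy (kJ/mol)", main = "best folding pathway")
  }
  invisible(x)
}
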