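# Artifact serialization: roadmap JSON, run configuration, and the
# end-to-end pipeline driver.

#' Serialize a fitted roadmap to JSON
#'
#' Writes a self-contained JSON graph file: the topology (sequence, native
#' torsions, segments), the nodes (id, torsions, energy) in insertion order,
#' and the directed weighted edges with method provenance. The output is
#' deterministic: the same fit serializes to identical bytes.
#'
#' @param fit a \code{\link{prm_fold}} object (or a \code{\link{roadmap}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_roadmap_json <- function(fit, path) {
  rm_ <- if (inherits(fit, "prm_fold")) fit$roadmap else fit
  topo <- rm_$topo
  nodes <- lapply(rm_$env$ids, function(id) {
    cc <- rm_$env$nodes[[id]]
    list(id = id, torsions = cc$torsions, energy = cc$energy)
  })
  obj <- list(
    topology = list(sequence = topo$sequence,
                    native_torsions = topo$native_torsions,
                    segments = topo$segments,
                    hydrophobic = topo$hydrophobic),
    nodes = nodes,
    edges = roadmap_edges(rm_))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a roadmap JSON file back into a roadmap object
#'
#' Reconstructs the topology, nodes and edges written by
#' \code{\link{write_roadmap_json}}; analysis functions (pathway extraction,
#' quality, formation orders) work on the result.
#'
#' @param path JSON file path.
#' @param model an \code{\link{energy_model}} for derived quantities.
#' @return a \code{\link{roadmap}}.
#' @export
read_roadmap_json <- function(path, model = energy_model()) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tp <- obj$topology
  topo <- protein_topology(tp$sequence, tp$native_torsions,
                           segments = tp$segments,
                           hydrophobic = tp$hydrophobic)
  rm_ <- roadmap(topo, model)
  nd <- obj$nodes
  for (i in seq_len(nrow(nd))) {
    tors <- if (is.list(nd$torsions)) nd$torsions[[i]] else nd$torsions[i, ]
    add_node(rm_, conformation(as.numeric(tors), id = nd$id[i],
                               energy = nd$energy[i]))
  }
  ed <- obj$edges
  if (length(ed) && nrow(ed)) {
    rm_$env$edges <- lapply(seq_len(nrow(ed)), function(i)
      list(from = ed$from[i], to = ed$to[i], weight = ed$weight[i],
           method = ed$method[i], step = as.integer(ed$step[i])))
  }
  rm_
}

#' Assemble and validate a run configuration
#'
#' All tunables of the pipeline with their defaults; unknown fields are
#' rejected. Either \code{pdb} (path to a native structure) or \code{toy}
#' (arguments for \code{\link{make_toy_protein}}) names the input protein.
#'
#' @param strategy connection strategy (see \code{\link{prm_fold}}).
#' @param seed root seed; stage seeds are derived from it (toy generation
#'   uses \code{seed}, the roadmap build uses \code{seed + 1}).
#' @param k,nf_local,gamma,alpha,kT,resolution,batch,max_batches,
#'   stability_threshold,perturb_magnitude,unfolded_quantile as in
#'   \code{\link{prm_fold}} / \code{\link{energy_model}}.
#' @param toy list of arguments for \code{\link{make_toy_protein}}.
#' @param pdb optional path to a native PDB file (overrides \code{toy}).
#' @return a validated list of class \code{"run_config"}.
#' @export
run_config <- function(strategy = "anc-local", seed = 1L, k = 20L,
                       nf_local = 40L, gamma = 0.1, alpha = 0.5, kT = 1,
                       resolution = 5, batch = 20L, max_batches = 8L,
                       stability_threshold = 30, perturb_magnitude = 30,
                       unfolded_quantile = 0.9,
                       toy = list(n = 8L, plan = "helix"), pdb = NULL) {
  cfg <- list(strategy = strategy, seed = as.integer(seed), k = as.integer(k),
              nf_local = as.integer(nf_local), gamma = gamma, alpha = alpha,
              kT = kT, resolution = resolution, batch = as.integer(batch),
              max_batches = as.integer(max_batches),
              stability_threshold = stability_threshold,
              perturb_magnitude = perturb_magnitude,
              unfolded_quantile = unfolded_quantile, toy = toy, pdb = pdb)
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys are the arguments of
#'   \code{\link{run_config}}; unknown keys raise an error.
#' @return a \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(run_config, x)
}

#' Run the full pipeline and write its artifacts
#'
#' Orchestrates fixture/input loading, sampling, connection and analysis
#' (\code{\link{prm_fold}}) and writes the artifact set into a directory:
#' \code{conformations.tsv}, \code{roadmap.json}, \code{pathways.txt},
#' \code{ssfo.tsv}, \code{method_report.tsv} and a machine-readable
#' \code{manifest.json} recording the full configuration. Identical
#' configuration and seed yield identical artifacts.
#'
#' @param config a \code{\link{run_config}} (or a path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @return the \code{\link{prm_fold}} fit, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  topo <- if (!is.null(config$pdb)) {
    read_native_pdb(config$pdb)
  } else {
    do.call(make_toy_protein, c(config$toy, list(seed = config$seed)))
  }
  model <- energy_model(kT = config$kT)
  fit <- prm_fold(topo, strategy = config$strategy, model = model,
                  batch = config$batch, max_batches = config$max_batches,
                  k = config$k, nf_local = config$nf_local,
                  gamma = config$gamma, alpha = config$alpha,
                  resolution = config$resolution,
                  perturb_magnitude = config$perturb_magnitude,
                  stability_threshold = config$stability_threshold,
                  unfolded_quantile = config$unfolded_quantile,
                  seed = config$seed + 1L)
  write_conformations(unname(fit$roadmap$env$nodes),
                      file.path(out_dir, "conformations.tsv"))
  write_roadmap_json(fit, file.path(out_dir, "roadmap.json"))
  pl <- vapply(fit$pathways, function(p)
    sprintf("%s\t%.12g", paste(p, collapse = ","), attr(p, "weight")),
    character(1L))
  writeLines(c("path\tweight", pl), file.path(out_dir, "pathways.txt"))
  utils::write.table(as.data.frame(fit$ssfo), file.path(out_dir, "ssfo.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fit$report),
                     file.path(out_dir, "method_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(config),
                   n_nodes = length(fit$roadmap$env$ids),
                   n_edges = nrow(fit$edges),
                   n_pathways = length(fit$pathways),
                   batches = fit$batches, stable = fit$stable,
                   pathway_quality = fit$quality,
                   energy_calls = energy_calls(fit$model))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(fit)
}
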