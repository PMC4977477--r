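# Shared fixtures, built in code. Kept tiny so the suite stays fast.

# plain 2-residue chain, no segments
tiny_topo <- function() {
  protein_topology(c("ALA", "SER"), c(180, -60, 60, 180))
}

# n-residue ideal helix with a single annotated segment
helix_topo <- function(n = 8L) {
  tors <- rep(c(-57, -47), n)
  tors[c(1L, 2L * n)] <- 180
  protein_topology(rep("ALA", n), tors,
                   segments = data.frame(label = "H1", kind = "helix",
                                         start = 0L, end = n))
}

# random conformation on a topology (terminal placeholders kept at 180)
random_conf <- function(topo, id) {
  tors <- stats::runif(2L * topo$n, -180, 180)
  tors[c(1L, 2L * topo$n)] <- 180
  conformation(tors, id = id)
}

# random partition of m units into at most k clusters, as a rigidity map
random_rigidity_map <- function(m, k = 4L) {
  structure(sample.int(k, m, replace = TRUE), class = "rigidity_map",
            n_units = m)
}

# brute-force disagreement count between two membership vectors
brute_rigidity_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  cnt <- 0L
  for (i in seq_len(length(a) - 1L))
    for (j in (i + 1L):length(a))
      cnt <- cnt + as.integer((a[i] == a[j]) != (b[i] == b[j]))
  cnt
}

# build a roadmap with hand-assigned nodes/edges for graph-level tests
manual_roadmap <- function(topo, energies, edges) {
  rm_ <- roadmap(topo, energy_model())
  for (id in names(energies))
    add_node(rm_, conformation(topo$native_torsions, id = id,
                               energy = energies[[id]]))
  rm_$env$edges <- lapply(seq_len(nrow(edges)), function(i)
    list(from = edges$from[i], to = edges$to[i], weight = edges$weight[i],
         method = "euclidean", step = i))
  rm_
}

# exhaustive path enumeration oracle (depth-first, simple paths only)
enumerate_best <- function(edges, from, to) {
  best <- Inf
  rec <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == to) { best <<- acc; return() }
    nxt <- edges[edges$from == node & !(edges$to %in% visited), ,
                 drop = FALSE]
    for (i in seq_len(nrow(nxt)))
      rec(nxt$to[i], c(visited, nxt$to[i]), acc + nxt$weight[i])
  }
  rec(from, from, 0)
  best
}

# independent straight transcription of the exponential-weight learner,
# used as the oracle for the bandit implementation
oracle_bandit_step <- function(w, gamma, alpha, ymin, ymax, chosen, success,
                               y, m = length(w)) {
  pstar <- (1 - gamma) * w / sum(w) + gamma / m
  if (success && is.finite(y)) {
    lo <- min(ymin, y); hi <- max(ymax, y)
    x <- if (hi == lo) 1 else alpha + (1 - alpha) * (1 - (y - lo) / (hi - lo))
    ymin <- lo; ymax <- hi
  } else x <- 0
  xs <- x / pstar[chosen]
  w[chosen] <- w[chosen] * exp(gamma * xs / m)
  list(w = w, ymin = ymin, ymax = ymax, x = x)
}
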