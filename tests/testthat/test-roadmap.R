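test_that("folding pathways are minimum-weight routes to native", {
  topo <- helix_topo(4)
  # u is the lone high-energy (unfolded) node; direct edge is costlier
  rm_ <- manual_roadmap(
    topo, c(native = 1, a = 5, u = 50),
    data.frame(from = c("u", "a", "u"), to = c("a", "native", "native"),
               weight = c(1, 1, 3)))
  paths <- extract_folding_pathways(rm_)
  expect_length(paths, 1L)
  expect_equal(as.character(paths[[1]]), c("u", "a", "native"))
  expect_equal(attr(paths[[1]], "weight"), 2)
  # single-edge graph
  rm2 <- manual_roadmap(topo, c(native = 1, u = 50),
                        data.frame(from = "u", to = "native", weight = 4))
  p2 <- extract_folding_pathways(rm2)
  expect_equal(attr(p2[[1]], "weight"), 4)
})

test_that("extracted path weights match exhaustive enumeration", {
  topo <- helix_topo(4)
  set.seed(81)
  for (g in 1:40) {
    nn <- sample(3:8, 1)
    ids <- c("native", "u", if (nn > 2) sprintf("v%d", seq_len(nn - 2)))
    en <- stats::setNames(c(1, 100, runif(nn - 2, 10, 50)), ids)
    ne <- sample(nn:(nn * (nn - 1)), 1)
    edges <- unique(data.frame(
      from = sample(ids, ne, replace = TRUE),
      to = sample(ids, ne, replace = TRUE)))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (!nrow(edges)) next
    edges$weight <- round(runif(nrow(edges), 0, 10), 3)
    rm_ <- manual_roadmap(topo, en, edges)
    oracle <- enumerate_best(edges, "u", "native")
    paths <- suppressMessages(extract_folding_pathways(rm_))
    if (is.infinite(oracle)) {
      expect_length(paths, 0L)
    } else {
      expect_length(paths, 1L)
      expect_equal(attr(paths[[1]], "weight"), oracle, tolerance = 1e-9)
    }
  }
})

test_that("pathway quality weighs edges by their pathway dominance", {
  topo <- helix_topo(4)
  rm_ <- manual_roadmap(
    topo, c(native = 1, a = 5, u = 50, w = 49),
    data.frame(from = c("u", "a", "w"), to = c("a", "native", "a"),
               weight = c(1, 2, 1.5)))
  p1 <- list(structure(c("u", "a", "native"), weight = 3))
  expect_equal(pathway_quality(rm_, p1), 3)      # each edge used once
  # shared edge a->native counts twice
  p2 <- c(p1, list(structure(c("w", "a", "native"), weight = 3.5)))
  expect_equal(pathway_quality(rm_, p2), 1 + 1.5 + 2 * 2)
  expect_equal(pathway_quality(rm_, list()), 0)
})

test_that("formation order detection follows segment contact appearance", {
  topo <- make_toy_protein(14, plan = "two-helix", seed = 2)
  expect_equal(topo$segments$label, c("H1", "H2"))
  h1 <- (topo$segments$start[1] + 1):topo$segments$end[1]
  h2 <- (topo$segments$start[2] + 1):topo$segments$end[2]
  nat <- topo$native_torsions
  ext <- rep(180, 2 * topo$n)
  half1 <- ext; half1[c(2 * h1 - 1, 2 * h1)] <- nat[c(2 * h1 - 1, 2 * h1)]
  half2 <- ext; half2[c(2 * h2 - 1, 2 * h2)] <- nat[c(2 * h2 - 1, 2 * h2)]
  mk <- function(tors, id, e) conformation(tors, id = id, energy = e)
  rm_ <- roadmap(topo, energy_model())
  for (cc in list(mk(nat, "native", 1), mk(half1, "m1", 10),
                  mk(half2, "m2", 10), mk(ext, "u", 100)))
    add_node(rm_, cc)
  # H1 forms first along u -> m1 -> native
  expect_equal(ssfo_of_path(rm_, c("u", "m1", "native")), c("H1", "H2"))
  # the mirrored path forms H2 first
  expect_equal(ssfo_of_path(rm_, c("u", "m2", "native")), c("H2", "H1"))
  # native-only path: every segment formed at the first step, native order
  expect_equal(ssfo_of_path(rm_, "native"), c("H1", "H2"))
  # distribution over both pathways
  dist <- ssfo_distribution(rm_, list(c("u", "m1", "native"),
                                      c("u", "m2", "native"),
                                      c("u", "m1", "native")))
  expect_equal(sum(dist$pct), 100)
  expect_equal(dominant_order(dist), "H1>H2")
  expect_true(validate_order(dist, "h1,h2"))
  expect_false(validate_order(dist, "H2>H1"))
})

test_that("dominant order breaks ties lexicographically with a warning", {
  d <- data.frame(order = c("B>A", "A>B"), pct = c(50, 50))
  class(d) <- c("ssfo_distribution", class(d))
  expect_warning(top <- dominant_order(d), "tie")
  expect_equal(top, "A>B")
  expect_error(dominant_order(d[0, ]), "empty")
})

test_that("stability compares successive distributions at the 30-point rule", {
  mk <- function(...) {
    d <- data.frame(order = names(list(...)),
                    pct = unlist(list(...)))
    class(d) <- c("ssfo_distribution", class(d)); d
  }
  expect_equal(ssfo_change(mk(A = 60, B = 40), mk(A = 60, B = 40)), 0)
  # an ordering moving 40 points is unstable; exactly 30 is stable
  expect_gt(ssfo_change(mk(A = 60, B = 40), mk(A = 20, B = 80)), 30)
  expect_lte(ssfo_change(mk(A = 60, B = 40), mk(A = 30, B = 70)), 30)
  # orderings absent on one side count at zero
  expect_equal(ssfo_change(mk(A = 100), mk(B = 100)), 100)
})

test_that("method report summarizes the attempt log", {
  log <- data.frame(step = 1:10, node = "q", method = "euclidean",
                    success = rep(c(TRUE, FALSE), c(4, 6)),
                    y = 1, cost = 2, reward = NA)
  rep_ <- method_report(log)
  expect_equal(rep_$success_rate, 0.4)
  expect_equal(rep_$usage_pct, 100)
  expect_equal(rep_$total_cost, 20)
  # multi-method usage percentages sum to 100 and match a raw re-scan
  set.seed(82)
  log2 <- data.frame(step = 1:50, node = "q",
                     method = sample(c("a", "b", "c"), 50, replace = TRUE),
                     success = runif(50) < 0.5, y = 1,
                     cost = sample(1:5, 50, replace = TRUE), reward = NA)
  r2 <- method_report(log2)
  expect_equal(sum(r2$usage_pct), 100)
  for (i in seq_len(nrow(r2))) {
    sub <- log2[log2$method == r2$method[i], ]
    expect_equal(r2$attempts[i], nrow(sub))
    expect_equal(r2$success_rate[i], mean(sub$success))
    expect_equal(r2$total_cost[i], sum(sub$cost))
  }
})

test_that("roadmap JSON serialization round-trips analysis quantities", {
  topo <- make_toy_protein(8, plan = "helix", seed = 1)
  fit <- prm_fold(topo, strategy = "euclidean", batch = 10, max_batches = 3,
                  k = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_roadmap_json(fit, f)
  back <- read_roadmap_json(f)
  expect_equal(sort(back$env$ids), sort(fit$roadmap$env$ids))
  expect_equal(roadmap_edges(back)$weight, fit$edges$weight)
  p0 <- extract_folding_pathways(fit$roadmap)
  p1 <- extract_folding_pathways(back)
  expect_equal(pathway_quality(back, p1), pathway_quality(fit$roadmap, p0))
  # quality is invariant to edge insertion order
  perm <- rev(seq_along(back$env$edges))
  back$env$edges <- back$env$edges[perm]
  expect_equal(pathway_quality(back, p1), pathway_quality(fit$roadmap, p0))
})
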