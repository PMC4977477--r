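test_that("cost-free selection probability mixes weights with uniform", {
  st <- bandit_state(c("A", "B"), gamma = 0.2)
  p <- selection_probability_no_cost(st)
  expect_equal(unname(p), c(0.5, 0.5))          # equal weights: uniform
  st$gamma <- 1
  st$w <- c(A = 10, B = 1)
  expect_equal(unname(selection_probability_no_cost(st)), c(0.5, 0.5))
  st$gamma <- 0                                  # pure weight ratio
  st$w <- c(A = 3, B = 1)
  expect_equal(unname(selection_probability_no_cost(st)), c(0.75, 0.25))
})

test_that("reward normalizes an edge weight between the running extrema", {
  st <- bandit_state(c("A", "B"), alpha = 0.5)
  st$ymin <- 2; st$ymax <- 5
  expect_equal(bandit_reward(2, st), 1)          # best weight seen
  expect_equal(bandit_reward(5, st), 0.5)        # worst weight seen: alpha
  expect_equal(bandit_reward(3.5, st), 0.75)
  # first observation: degenerate extrema give full reward
  fresh <- bandit_state(c("A", "B"), alpha = 0.3)
  expect_equal(bandit_reward(7, fresh), 1)
})

test_that("weight updates are exponential in the importance-weighted reward", {
  st <- bandit_state(c("A", "B"), gamma = 0.5)
  st0 <- update_weights(st, "A", 0)
  expect_equal(st0$w, st$w)                      # zero reward: no change
  # uniform p* = 0.5, x = 1: x* = 2, factor exp(0.5 * 2 / 2) = e^0.5
  st1 <- update_weights(st, "A", 1)
  expect_equal(st1$w[["A"]], exp(0.5))
  expect_equal(st1$w[["B"]], 1)
  # repeated reward drives selection probability to its ceiling (1-g) + g/m
  st <- bandit_state(c("A", "B"), gamma = 0.1)
  prev <- selection_probability_no_cost(st)[["A"]]
  for (k in 1:150) {
    st <- update_weights(st, "A", 1)
    p <- selection_probability_no_cost(st)[["A"]]
    expect_gt(p, prev)
    prev <- p
  }
  expect_lt(prev, 0.9 + 0.1 / 2)
  expect_gt(prev, 0.9)
})

test_that("cost adjustment divides by average cost and renormalizes", {
  st <- bandit_state(c("A", "B"), gamma = 0.1)
  expect_equal(unname(cost_adjusted_probability(st)), c(0.5, 0.5))
  st$cost_sum <- c(A = 10, B = 40); st$cost_n <- c(A = 10, B = 20)
  # p* uniform, costs (1, 2): (2/3, 1/3)
  expect_equal(unname(cost_adjusted_probability(st)), c(2 / 3, 1 / 3))
  # probabilities always sum to one on random states
  set.seed(71)
  for (k in 1:20) {
    st$w <- stats::setNames(runif(2, 0.1, 5), c("A", "B"))
    st$cost_sum <- stats::setNames(runif(2, 1, 100), c("A", "B"))
    st$cost_n <- stats::setNames(sample(0:5, 2, replace = TRUE), c("A", "B"))
    expect_equal(sum(cost_adjusted_probability(st)), 1, tolerance = 1e-12)
    expect_equal(sum(selection_probability_no_cost(st)), 1, tolerance = 1e-12)
  }
})

test_that("the learner matches an independent transcription step by step", {
  set.seed(72)
  methods <- c("A", "B", "C")
  st <- bandit_state(methods, gamma = 0.07, alpha = 0.4)
  w <- st$w; ymin <- Inf; ymax <- -Inf
  for (t in 1:200) {
    chosen <- sample(methods, 1)
    success <- runif(1) < 0.6
    y <- runif(1, 0, 10)
    cost <- sample(1:30, 1)
    st <- bandit_observe(st, chosen, success, y, cost)$state
    o <- oracle_bandit_step(w, 0.07, 0.4, ymin, ymax, chosen, success, y)
    w <- o$w; ymin <- o$ymin; ymax <- o$ymax
    expect_equal(unname(st$w), unname(w), tolerance = 1e-12)
  }
})

test_that("selection keeps the exploration floor at all times", {
  set.seed(73)
  st <- bandit_state(c("A", "B", "C"), gamma = 0.12)
  for (t in 1:300) {
    st <- bandit_observe(st, sample(c("A", "B", "C"), 1),
                         runif(1) < 0.5, runif(1, 0, 4), 1)$state
    p <- selection_probability_no_cost(st)
    expect_true(all(p >= 0.12 / 3 - 1e-12))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("cold start is uniform and replay is deterministic", {
  log <- attempt_log(4L)
  p <- anc_local_probabilities(c(0, 0, 0, 0), log, c("A", "B", "C"))
  expect_equal(unname(p), rep(1 / 3, 3))
  # seed a history and check replay determinism
  set.seed(74)
  for (t in 1:60)
    log_append(log, sprintf("n%d", t), runif(4, -180, 180),
               sample(c("A", "B", "C"), 1), runif(1) < 0.5,
               runif(1, 1, 3), sample(1:20, 1))
  q <- c(10, 20, 30, 40)
  p1 <- anc_local_probabilities(q, log, c("A", "B", "C"))
  p2 <- anc_local_probabilities(q, log, c("A", "B", "C"))
  expect_identical(p1, p2)
  set.seed(75); m1 <- sample_method(p1)
  set.seed(75); m2 <- sample_method(p1)
  expect_identical(m1, m2)
})

test_that("local replay prefers the locally successful method", {
  # region around the query: B always succeeds; far away: A always succeeds
  log <- attempt_log(4L)
  set.seed(76)
  for (t in 1:60)   # far-away A successes dominate the global picture
    log_append(log, sprintf("far%d", t), rep(150, 4) + runif(4, -5, 5),
               "A", TRUE, runif(1, 1, 2), 1)
  for (t in 1:40)   # near the query, B succeeds and A fails
    log_append(log, sprintf("near%d", t), runif(4, -10, 10),
               if (t %% 2) "B" else "A", t %% 2 == 1,
               if (t %% 2) runif(1, 1, 2) else Inf, 1)
  p <- anc_local_probabilities(rep(0, 4), log, c("A", "B"), nf_local = 40)
  expect_gt(p[["B"]], 0.5)
  expect_gt(p[["B"]], p[["A"]])
})

test_that("on a stationary bench the better arm dominates selection", {
  bench <- make_two_region_bench(p_favored = 0.8, p_other = 0.2,
                                 region_prob = c(1, 0), y_range = c(1, 1))
  freq <- vapply(1:5, function(s) {
    tr <- run_bench(bench, "anc-global", steps = 500, gamma = 0.1, seed = s)
    mean(tr$method == "A")
  }, numeric(1))
  expect_gt(mean(freq), 0.6)
})

test_that("local learning beats global learning on the two-region bench", {
  wins <- 0L
  for (s in 1:6) {
    bench <- make_two_region_bench()
    loc <- run_bench(bench, "anc-local", steps = 250, seed = s)
    glo <- run_bench(bench, "anc-global", steps = 250, seed = s)
    half <- 126:250
    if (mean(loc$correct[half]) > mean(glo$correct[half])) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})
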