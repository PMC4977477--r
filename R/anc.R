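# Adaptive Neighbor Connection: an Exp3-style adversarial bandit over
# candidate connection methods, with a cost-adjusted selection probability
# and (for the local variant) per-query replay of the attempt history
# recorded in the neighbourhood of the query conformation.

#' Bandit state over connection methods
#'
#' Holds the exponential weights (initialized to 1), the exploration rate
#' gamma, the reward floor alpha, the running edge-weight extrema used to
#' normalize rewards, and per-method cost accumulators.
#'
#' @param methods character vector of method ids (unique, length m >= 1).
#' @param gamma exploration constant in (0, 1]; every method retains
#'   selection probability at least gamma/m.
#' @param alpha reward floor in [0, 1): a successful attempt is rewarded in
#'   [alpha, 1] depending on where its edge weight falls between the best and
#'   worst weights seen.
#' @return An object of class \code{"bandit_state"}.
#' @export
bandit_state <- function(methods, gamma = 0.1, alpha = 0.5) {
  methods <- as.character(methods)
  stopifnot(length(methods) >= 1L, !anyDuplicated(methods),
            gamma > 0, gamma <= 1, alpha >= 0, alpha < 1)
  w <- stats::setNames(rep(1, length(methods)), methods)
  z <- stats::setNames(rep(0, length(methods)), methods)
  structure(list(methods = methods, w = w, gamma = gamma, alpha = alpha,
                 ymin = Inf, ymax = -Inf, cost_sum = z, cost_n = z),
            class = "bandit_state")
}

#' @export
print.bandit_state <- function(x, ...) {
  cat(sprintf("Bandit state over %d methods (gamma=%g, alpha=%g)\n",
              length(x$methods), x$gamma, x$alpha))
  p <- cost_adjusted_probability(x)
  for (mid in x$methods)
    cat(sprintf("  %-10s w=%.4g p=%.3f avg cost=%.3g\n", mid, x$w[[mid]],
                p[[mid]], .avg_costs(x)[[mid]]))
  invisible(x)
}

#' Cost-free selection probabilities
#'
#' The Exp3 mixture of the normalized weights and the uniform distribution:
#' \code{p*_i = (1 - gamma) w_i / sum(w) + gamma / m}. Sums to 1 and every
#' component is at least gamma/m.
#'
#' @param state a \code{\link{bandit_state}}.
#' @return named probability vector over methods.
#' @export
selection_probability_no_cost <- function(state) {
  m <- length(state$w)
  (1 - state$gamma) * state$w / sum(state$w) + state$gamma / m
}

#' Reward of a successful connection attempt
#'
#' Normalizes the attempt's edge weight y against the extrema recorded so
#' far: \code{x = alpha + (1 - alpha) (1 - (y - min) / (max - min))}, so the
#' best-seen weight earns 1 and the worst earns alpha. With a single
#' observation (min = max) the reward is 1. The extrema are taken after
#' including y itself. Unchosen methods and failed attempts are rewarded 0
#' elsewhere; this function only evaluates the produced edge.
#'
#' @param y edge weight of the produced edge (finite).
#' @param state a \code{\link{bandit_state}} carrying the running extrema.
#' @return reward in [alpha, 1].
#' @export
bandit_reward <- function(y, state) {
  lo <- min(state$ymin, y)
  hi <- max(state$ymax, y)
  if (hi == lo) return(1)
  state$alpha + (1 - state$alpha) * (1 - (y - lo) / (hi - lo))
}

#' Exponential weight update
#'
#' Importance-weights the reward by the chosen method's cost-free selection
#' probability (\code{x* = x / p*_i}) and multiplies its weight by
#' \code{exp(gamma x* / m)}; all other methods receive reward 0 and keep
#' their weight.
#'
#' @param state a \code{\link{bandit_state}}.
#' @param method id of the chosen method.
#' @param x reward in [0, 1].
#' @return the updated \code{\link{bandit_state}}.
#' @export
update_weights <- function(state, method, x) {
  stopifnot(method %in% state$methods, x >= 0, x <= 1)
  pstar <- selection_probability_no_cost(state)
  m <- length(state$w)
  state$w[[method]] <- state$w[[method]] *
    exp(state$gamma * (x / pstar[[method]]) / m)
  state
}

.avg_costs <- function(state) {
  # unseen methods get the optimistic unit cost so Eq-11 never starves them
  ifelse(state$cost_n > 0, state$cost_sum / pmax(state$cost_n, 1), 1)
}

#' Cost-adjusted selection probabilities
#'
#' Divides each cost-free probability by the method's average cost (energy
#' calls per attempt; methods never attempted count 1) and renormalizes:
#' \code{p_i = (p*_i / c_i) / sum_j (p*_j / c_j)}.
#'
#' @param state a \code{\link{bandit_state}}.
#' @return named probability vector over methods, summing to 1.
#' @export
cost_adjusted_probability <- function(state) {
  pstar <- selection_probability_no_cost(state)
  v <- pstar / .avg_costs(state)
  v / sum(v)
}

#' Record an attempt outcome in a bandit state
#'
#' Updates the edge-weight extrema (successful attempts only), computes the
#' reward (\code{\link{bandit_reward}} on success, 0 on failure), applies the
#' exponential weight update for the chosen method, and accumulates its cost.
#'
#' @param state a \code{\link{bandit_state}}.
#' @param method id of the method that made the attempt.
#' @param success did the local planner produce an edge?
#' @param y edge weight of the produced edge (ignored when
#'   \code{success = FALSE}).
#' @param cost energy calls incurred by the attempt (>= 0).
#' @return list with the updated \code{state} and the \code{reward} granted.
#' @export
bandit_observe <- function(state, method, success, y = Inf, cost = 0) {
  if (isTRUE(success) && is.finite(y)) {
    x <- bandit_reward(y, state)
    state$ymin <- min(state$ymin, y)
    state$ymax <- max(state$ymax, y)
  } else {
    x <- 0
  }
  state <- update_weights(state, method, x)
  state$cost_sum[[method]] <- state$cost_sum[[method]] + cost
  state$cost_n[[method]] <- state$cost_n[[method]] + 1
  list(state = state, reward = x)
}

#' Sample a method id from a probability vector
#'
#' Inverse-CDF sampling in method-id order, so a single uniform draw maps
#' deterministically to a method.
#'
#' @param p named probability vector (sums to 1).
#' @param u uniform draw in [0, 1); by default taken from the RNG stream.
#' @return the selected method id.
#' @export
sample_method <- function(p, u = stats::runif(1L)) {
  cdf <- cumsum(p)
  names(p)[min(which(u < cdf + 1e-15))]
}

# ---------------------------------------------------------------------------
# Attempt history store: one record per connection attempt, with the query
# node's torsions kept so later queries can replay their neighbourhood.

#' Create an attempt log
#'
#' Append-only store of connection-attempt records: step, query node id and
#' torsions, method, success, edge weight, energy-call cost, and the reward
#' granted at attempt time. The torsions are retained so the local learner
#' can find the nearest prior attempts to a new query.
#'
#' @param n_torsions torsion dimension of the conformations logged.
#' @return An object of class \code{"attempt_log"}.
#' @export
attempt_log <- function(n_torsions) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  cap <- 64L
  env$step <- integer(cap)
  env$node <- character(cap)
  env$method <- character(cap)
  env$success <- logical(cap)
  env$y <- numeric(cap)
  env$cost <- numeric(cap)
  env$reward <- numeric(cap)
  env$tors <- matrix(NA_real_, cap, n_torsions)
  structure(list(env = env, n_torsions = n_torsions),
            class = "attempt_log")
}

#' @rdname attempt_log
#' @param log an \code{"attempt_log"}.
#' @export
log_size <- function(log) log$env$n

#' @rdname attempt_log
#' @param node query node id.
#' @param tors torsion vector of the query node.
#' @param method method id that made the attempt.
#' @param success,y,cost,reward attempt outcome: planner success, edge weight
#'   (\code{Inf} on failure), energy-call cost, and the reward granted at
#'   attempt time (optional).
#' @export
log_append <- function(log, node, tors, method, success, y, cost,
                       reward = NA_real_) {
  e <- log$env
  n <- e$n + 1L
  if (n > length(e$step)) {            # grow by doubling
    grow <- function(v) { length(v) <- 2L * length(v); v }
    e$step <- grow(e$step); e$node <- grow(e$node)
    e$method <- grow(e$method); e$success <- grow(e$success)
    e$y <- grow(e$y); e$cost <- grow(e$cost); e$reward <- grow(e$reward)
    t2 <- matrix(NA_real_, 2L * nrow(e$tors), ncol(e$tors))
    t2[seq_len(e$n), ] <- e$tors[seq_len(e$n), ]
    e$tors <- t2
  }
  e$n <- n
  e$step[n] <- n
  e$tors[n, ] <- tors
  e$node[n] <- node
  e$method[n] <- method
  e$success[n] <- success
  e$y[n] <- y
  e$cost[n] <- cost
  e$reward[n] <- reward
  invisible(log)
}

#' @export
as.data.frame.attempt_log <- function(x, ...) {
  e <- x$env
  i <- seq_len(e$n)
  data.frame(step = e$step[i], node = e$node[i], method = e$method[i],
             success = e$success[i], y = e$y[i], cost = e$cost[i],
             reward = e$reward[i], stringsAsFactors = FALSE)
}

# circular RMS distances between one torsion vector and the logged records
.log_distances <- function(log, tors) {
  e <- log$env
  i <- seq_len(e$n)
  d <- normalize_angle(sweep(e$tors[i, , drop = FALSE], 2L, tors))
  sqrt(rowSums(d^2) / length(tors))
}

#' Local selection probabilities by neighbourhood replay
#'
#' The localized learner: finds the \code{nf_local} prior attempt records
#' whose query nodes are nearest (torsional Euclidean distance) to the
#' current query, replays them in chronological order through a fresh bandit
#' state — re-deriving rewards from the recorded edge weights, with extrema
#' tracked over the replayed records only — and returns the resulting
#' cost-adjusted selection probabilities. With an empty history this is the
#' uniform cold start.
#'
#' @param tors torsion vector of the query conformation.
#' @param log an \code{\link{attempt_log}}.
#' @param methods character vector of candidate method ids.
#' @param gamma,alpha bandit constants (see \code{\link{bandit_state}}).
#' @param nf_local size of the local learning region (number of nearest
#'   attempt records replayed; 40 by default).
#' @return named probability vector over methods.
#' @export
anc_local_probabilities <- function(tors, log, methods, gamma = 0.1,
                                    alpha = 0.5, nf_local = 40L) {
  state <- bandit_state(methods, gamma, alpha)
  n <- log_size(log)
  if (n == 0L) return(cost_adjusted_probability(state))
  d <- .log_distances(log, tors)
  ord <- order(d, seq_len(n))           # ties by record order
  take <- sort(ord[seq_len(min(nf_local, n))])  # chronological replay
  e <- log$env
  for (i in take) {
    state <- bandit_observe(state, e$method[i], e$success[i],
                            e$y[i], e$cost[i])$state
  }
  cost_adjusted_probability(state)
}
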