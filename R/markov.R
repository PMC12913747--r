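# Markov engine: evolve a strategy through the ten-state (+ Dead) model
# over the horizon, accruing discounted costs and QALYs, via a
# deterministic cohort recursion or a seeded individual-level
# microsimulation.

#' Define one strategy's complete economic model
#'
#' @param arm Arm label (`"surgical"`, `"medical"`, ...).
#' @param entrance Probability vector over the ten living states (sums
#'   to 1); where survivors of the perioperative tree (or medical
#'   patients directly) enter the Markov model.
#' @param cycle1_matrix `transition_matrix` governing cycle 1.
#' @param steady_matrix `transition_matrix` governing cycles 2..horizon.
#'   Defaults to `cycle1_matrix` when `NULL`.
#' @param cost_rule `"state_indexed"` (annual Markov state costs,
#'   default for the surgical arm), `"fixed"` (a flat annual cost,
#'   default for the medical arm) or `"both"`.
#' @param fixed_cost_param Parameter name (or a number) supplying the
#'   flat annual cost under `"fixed"`/`"both"` (e.g. `"cMedical"`).
#' @param revision_param Parameter name (or a number) for the per-cycle
#'   probability of revision surgery (`"pRevisionESS"` for the surgical
#'   arm, 0 for medical). Each revision adds the expected (cohort) or a
#'   sampled (microsim) perioperative-tree traversal cost.
#' @param use_tree Traverse the perioperative decision tree at entry
#'   (surgical arm) or enter the Markov model directly (medical arm).
#' @param state_cost_orientation Passed to [state_costs()].
#' @param background_mortality Optional numeric vector of per-cycle
#'   all-cause death probabilities (length >= horizon), applied after
#'   each transition. Default `NULL`: the only route to Dead is surgical
#'   death.
#' @return Object of class `strategy_model`.
#' @export
strategy_model <- function(arm, entrance, cycle1_matrix, steady_matrix = NULL,
                           cost_rule = c("state_indexed", "fixed", "both"),
                           fixed_cost_param = "cMedical",
                           revision_param = 0,
                           use_tree = FALSE,
                           state_cost_orientation = "healthiest_cheapest",
                           background_mortality = NULL) {
  cost_rule <- match.arg(cost_rule)
  entrance <- as.numeric(entrance)
  if (length(entrance) != N_STATES) stop("entrance must have length 10")
  if (any(entrance < 0) || abs(sum(entrance) - 1) > 1e-9) {
    stop("entrance must be a probability vector summing to 1")
  }
  if (is.null(steady_matrix)) steady_matrix <- cycle1_matrix
  m1 <- tm_matrix(cycle1_matrix)
  occupied <- which(entrance > 0)
  dead_rows <- occupied[rowSums(m1)[occupied] == 0]
  if (length(dead_rows)) {
    stop("entrance places mass on state(s) with no observed transitions ",
         "in the cycle-1 matrix: ",
         paste(state_bin_labels()[dead_rows], collapse = ", "))
  }
  structure(list(arm = arm, entrance = entrance,
                 cycle1_matrix = cycle1_matrix,
                 steady_matrix = steady_matrix,
                 cost_rule = cost_rule,
                 fixed_cost_param = fixed_cost_param,
                 revision_param = revision_param,
                 use_tree = use_tree,
                 state_cost_orientation = state_cost_orientation,
                 background_mortality = background_mortality),
            class = "strategy_model")
}

resolve_param <- function(x, params) {
  if (is.character(x)) unname(param_value(params, x)) else as.numeric(x)
}

# States reachable at the start of any cycle must have outgoing
# transitions; otherwise cohort mass would silently stall in a state the
# data say nothing about.
check_reachability <- function(strategy) {
  m1 <- tm_matrix(strategy$cycle1_matrix)
  ms <- tm_matrix(strategy$steady_matrix)
  reach <- strategy$entrance > 0
  bad <- which(reach & rowSums(m1) == 0)
  if (!length(bad)) {
    # one cycle-1 step, then closure under the steady matrix
    reach <- as.vector(reach %*% (m1 > 0)) > 0
    repeat {
      bad <- which(reach & rowSums(ms) == 0)
      if (length(bad)) break
      nxt <- (as.vector(reach %*% (ms > 0)) > 0) | reach
      if (identical(nxt, reach)) break
      reach <- nxt
    }
  }
  if (length(bad)) {
    stop("reachable state(s) with no observed transitions (all-zero row): ",
         paste(state_bin_labels()[bad], collapse = ", "),
         "; supply a matrix covering them or patch_unobserved_rows()")
  }
  invisible(TRUE)
}

per_cycle_state_cost <- function(strategy, params) {
  sc <- switch(strategy$cost_rule,
    state_indexed = state_costs(params, strategy$state_cost_orientation),
    fixed = rep(0, N_STATES),
    both = state_costs(params, strategy$state_cost_orientation))
  fc <- if (strategy$cost_rule %in% c("fixed", "both")) {
    resolve_param(strategy$fixed_cost_param, params)
  } else 0
  list(state = sc, fixed = fc)
}

#' Evaluate a strategy as a deterministic cohort recursion
#'
#' The surgical arm traverses the perioperative tree in expectation: the
#' death-path mass moves to Dead (its cost, including the cost of death,
#' is part of the expected tree cost) and survivors enter the Markov
#' model at the entrance distribution. Cycle 1 then uses the cycle-1
#' matrix and cycles 2..H the steady matrix; each cycle accrues the
#' post-transition occupancy's utility and cost, plus the expected
#' revision cost, discounted by `(1+r)^-(t-1)`. No half-cycle
#' correction is applied.
#'
#' @param strategy A `strategy_model`.
#' @param config A `model_config`.
#' @param params A `parameter_set`.
#' @return Object of class `cohort_result`: discounted `cost` and
#'   `qalys`, the per-cycle occupancy `trace` (rows = cycles 0..H,
#'   columns = ten states plus `Dead`), and the entry-level quantities.
#' @export
run_cohort <- function(strategy, config, params) {
  stopifnot(inherits(strategy, "strategy_model"),
            inherits(config, "model_config"),
            inherits(params, "parameter_set"))
  check_reachability(strategy)
  H <- config$horizon_years
  u <- state_utilities()
  cc <- per_cycle_state_cost(strategy, params)
  rev_p <- resolve_param(strategy$revision_param, params)

  tree <- NULL; tree_cost <- 0; d0 <- 0; entry_cost <- 0
  if (strategy$use_tree || rev_p > 0) {
    tree <- build_perioperative_tree(params)
    tree_cost <- expected_perioperative_cost(tree)
  }
  if (strategy$use_tree) {
    out <- enumerate_outcomes(tree)
    d0 <- sum(out$probability[out$disposition == "death"])
    entry_cost <- tree_cost
  }
  q <- strategy$background_mortality
  if (!is.null(q) && length(q) < H) {
    stop("background_mortality must cover the whole horizon")
  }

  m1 <- tm_matrix(strategy$cycle1_matrix)
  ms <- tm_matrix(strategy$steady_matrix)
  v <- (1 - d0) * strategy$entrance
  dead <- d0
  trace <- matrix(0, H + 1, N_STATES + 1,
                  dimnames = list(NULL, c(state_bin_labels(), "Dead")))
  trace[1, ] <- c(v, dead)
  cost <- entry_cost; qalys <- 0
  for (t in seq_len(H)) {
    v <- as.vector(v %*% (if (t == 1) m1 else ms))
    if (!is.null(q) && q[t] > 0) {
      dead <- dead + sum(v) * q[t]
      v <- v * (1 - q[t])
    }
    alive <- sum(v)
    dq <- (1 + config$discount_rate_qalys)^(-(t - 1))
    dc <- (1 + config$discount_rate_costs)^(-(t - 1))
    qalys <- qalys + dq * sum(v * u)
    cycle_cost <- sum(v * cc$state) + alive * cc$fixed +
      alive * rev_p * tree_cost
    cost <- cost + dc * cycle_cost
    trace[t + 1, ] <- c(v, dead)
  }
  structure(list(arm = strategy$arm, cost = cost, qalys = qalys,
                 trace = trace, entry_cost = entry_cost,
                 death_at_entry = d0, tree_cost = tree_cost,
                 revision_probability = rev_p),
            class = "cohort_result")
}

#' Evaluate a strategy by individual-level microsimulation
#'
#' Simulates `n` independent patient trajectories: a sampled
#' perioperative-tree outcome (surgical arm), a sampled state path, and
#' sampled per-cycle revision events whose cost is a fresh tree-outcome
#' draw. Reproducible for a given `seed`; its means converge to
#' [run_cohort()].
#'
#' @inheritParams run_cohort
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @return Object of class `microsim_result`: data frame `individuals`
#'   (`cost`, `qalys` per person), plus means and standard errors.
#' @export
run_microsim <- function(strategy, config, params, n = config$n_microsim_individuals,
                         seed = config$rng_seed) {
  stopifnot(n >= 1)
  check_reachability(strategy)
  set.seed(seed)
  H <- config$horizon_years
  u <- state_utilities()
  cc <- per_cycle_state_cost(strategy, params)
  rev_p <- resolve_param(strategy$revision_param, params)

  tree <- NULL; tree_out <- NULL
  if (strategy$use_tree || rev_p > 0) {
    tree <- build_perioperative_tree(params)
    tree_out <- enumerate_outcomes(tree)
  }
  cost <- numeric(n); qalys <- numeric(n)
  if (strategy$use_tree) {
    draw <- sample.int(nrow(tree_out), n, replace = TRUE,
                       prob = tree_out$probability)
    cost <- tree_out$cost[draw]
    alive <- tree_out$disposition[draw] != "death"
  } else {
    alive <- rep(TRUE, n)
  }
  state <- rep(NA_integer_, n)
  state[alive] <- sample.int(N_STATES, sum(alive), replace = TRUE,
                             prob = strategy$entrance)
  m1 <- tm_matrix(strategy$cycle1_matrix)
  ms <- tm_matrix(strategy$steady_matrix)
  q <- strategy$background_mortality

  for (t in seq_len(H)) {
    m <- if (t == 1) m1 else ms
    idx_alive <- which(alive)
    if (!length(idx_alive)) break
    st <- state[idx_alive]
    for (s in unique(st)) {
      who <- idx_alive[st == s]
      if (all(m[s, ] == 0)) {
        stop("individual in state ", state_bin_labels()[s],
             " with no observed transitions")
      }
      state[who] <- sample.int(N_STATES, length(who), replace = TRUE,
                               prob = m[s, ])
    }
    if (!is.null(q) && q[t] > 0) {
      dies <- stats::runif(length(idx_alive)) < q[t]
      alive[idx_alive[dies]] <- FALSE
      state[idx_alive[dies]] <- NA_integer_
      idx_alive <- idx_alive[!dies]
    }
    dq <- (1 + config$discount_rate_qalys)^(-(t - 1))
    dc <- (1 + config$discount_rate_costs)^(-(t - 1))
    st <- state[idx_alive]
    qalys[idx_alive] <- qalys[idx_alive] + dq * u[st]
    cyc <- cc$state[st] + cc$fixed
    if (rev_p > 0) {
      has_rev <- stats::runif(length(idx_alive)) < rev_p
      if (any(has_rev)) {
        rev_draw <- sample.int(nrow(tree_out), sum(has_rev), replace = TRUE,
                               prob = tree_out$probability)
        cyc[has_rev] <- cyc[has_rev] + tree_out$cost[rev_draw]
      }
    }
    cost[idx_alive] <- cost[idx_alive] + dc * cyc
  }
  ind <- data.frame(cost = cost, qalys = qalys)
  structure(list(arm = strategy$arm, individuals = ind,
                 mean_cost = mean(cost), mean_qalys = mean(qalys),
                 se_cost = stats::sd(cost) / sqrt(n),
                 se_qalys = stats::sd(qalys) / sqrt(n),
                 n = n, seed = seed),
            class = "microsim_result")
}

#' Per-cycle revision-surgery cost
#'
#' In `"expected"` mode returns the per-cycle expected revision cost,
#' `P(revision) * E[tree traversal cost]`. In `"sampled"` mode draws
#' Bernoulli revision events and, for each event, a tree outcome; the
#' death branch is priced (cESS + cDeath) but — as in the cohort
#' recursion — a revision never changes the occupant's state.
#'
#' @param params A `parameter_set`.
#' @param tree Perioperative tree from [build_perioperative_tree()].
#' @param mode `"expected"` or `"sampled"`.
#' @param n Number of cycles to sample (sampled mode).
#' @param revision_param Parameter name or numeric probability.
#' @return Expected mode: a single USD value. Sampled mode: data frame
#'   with columns `revision` (logical), `cost`, `death_path` (logical).
#' @export
apply_revision <- function(params, tree, mode = c("expected", "sampled"),
                           n = 1, revision_param = "pRevisionESS") {
  mode <- match.arg(mode)
  rev_p <- resolve_param(revision_param, params)
  if (mode == "expected") {
    return(rev_p * expected_perioperative_cost(tree))
  }
  out <- enumerate_outcomes(tree)
  has_rev <- stats::runif(n) < rev_p
  cost <- numeric(n); death <- logical(n)
  if (any(has_rev)) {
    draw <- sample.int(nrow(out), sum(has_rev), replace = TRUE,
                       prob = out$probability)
    cost[has_rev] <- out$cost[draw]
    death[has_rev] <- out$disposition[draw] == "death"
  }
  data.frame(revision = has_rev, cost = cost, death_path = death)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> arm = %s\n", x$arm))
  cat(sprintf("  discounted cost:  $%.2f\n", x$cost))
  cat(sprintf("  discounted QALYs: %.4f\n", x$qalys))
  if (x$death_at_entry > 0) {
    cat(sprintf("  perioperative death mass: %.6f\n", x$death_at_entry))
  }
  invisible(x)
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> arm = %s (n = %d, seed = %d)\n",
              x$arm, x$n, x$seed))
  cat(sprintf("  mean cost:  $%.2f (SE %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean QALYs: %.4f (SE %.4f)\n", x$mean_qalys, x$se_qalys))
  invisible(x)
}
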