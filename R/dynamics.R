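#' Deterministic strategy-average learning dynamics
#'
#' The mean-field limit of Expected SARSA self-play: sampled rewards and
#' next-state value estimates are replaced by their exact expectations under
#' the current joint epsilon-greedy strategy, giving a deterministic map on
#' the joint state-action-value space. It models idealised learning with an
#' infinite memory batch.
#'
#' @name avg_dynamics
NULL

#' Joint epsilon-greedy action frequencies of a joint value state
#'
#' @param q_list list of two value tables (one per agent).
#' @param epsilon exploration rate.
#' @return List of two 4 x 2 frequency tables, uniquely determined by the
#'   value tables and `epsilon` via the shared greedy tie rule.
#' @export
joint_frequencies <- function(q_list, epsilon) {
  stopifnot(length(q_list) == 2L)
  lapply(q_list, function(q) action_frequencies(greedy_strategy(q), epsilon))
}

# joint-action state index from agent i's action ai and co-player's action aj
joint_state_for <- function(agent, ai, aj) {
  if (agent == 1L) joint_to_state(ai, aj) else joint_to_state(aj, ai)
}

#' Strategy-average reward per state and own action
#'
#' `rbar_i(s, a)`: expected reward to agent `i` for taking action `a` in
#' state `s`, averaging the co-player's action under its frequencies and the
#' (here degenerate) state transition.
#'
#' @param game an [ipd_game()].
#' @param x list of two 4 x 2 action-frequency tables.
#' @param agent 1 or 2.
#' @return A 4 x 2 matrix.
#' @export
avg_reward_sa <- function(game, x, agent) {
  j <- 3L - agent
  out <- value_table(0)
  for (s in 1:4) for (ai in 1:2) {
    out[s, ai] <- sum(vapply(1:2, function(aj) {
      x[[j]][s, aj] * game$reward_next[agent, joint_state_for(agent, ai, aj)]
    }, numeric(1)))
  }
  out
}

#' Strategy-average transition kernel conditioned on one agent's action
#'
#' `pbar_i(s' | a, s)`: probability of the next state given agent `i` plays
#' `a` in `s`, marginalising the co-player's action.
#'
#' @inheritParams avg_reward_sa
#' @return A 4 x 2 x 4 array indexed `[s, a, s']`; each `[s, a, ]` slice is a
#'   probability vector.
#' @export
avg_transition_agent <- function(game, x, agent) {
  j <- 3L - agent
  p <- array(0, dim = c(4, 2, 4),
             dimnames = list(s = game$states, a = game$actions,
                             s_next = game$states))
  for (s in 1:4) for (ai in 1:2) for (aj in 1:2) {
    sn <- joint_state_for(agent, ai, aj)
    p[s, ai, sn] <- p[s, ai, sn] + x[[j]][s, aj]
  }
  p
}

#' Strategy-average joint state-transition matrix
#'
#' `pbar(s, s')`: transition matrix of the environment state under the joint
#' strategy, averaging over both agents' actions.
#'
#' @inheritParams avg_reward_sa
#' @return A 4 x 4 row-stochastic matrix.
#' @export
avg_transition_joint <- function(game, x) {
  p <- matrix(0, 4, 4, dimnames = list(s = game$states, s_next = game$states))
  for (s in 1:4) for (a1 in 1:2) for (a2 in 1:2) {
    sn <- joint_to_state(a1, a2)
    p[s, sn] <- p[s, sn] + x[[1]][s, a1] * x[[2]][s, a2]
  }
  p
}

#' Strategy-average reward per state
#'
#' `rbar_i(s)`: expected one-step reward to agent `i` from state `s` under
#' the joint strategy (both agents' actions averaged).
#'
#' @inheritParams avg_reward_sa
#' @return Length-4 numeric vector.
#' @export
avg_state_reward <- function(game, x, agent) {
  vapply(1:4, function(s) {
    sum(vapply(1:2, function(a1) sum(vapply(1:2, function(a2) {
      x[[1]][s, a1] * x[[2]][s, a2] *
        game$reward_next[agent, joint_to_state(a1, a2)]
    }, numeric(1))), numeric(1)))
  }, numeric(1))
}

#' Strategy-average state values via the Bellman linear system
#'
#' Solves `v = rbar + delta * pbar %*% v` by matrix inversion:
#' `v = (I - delta * pbar)^{-1} rbar`.
#'
#' @inheritParams avg_reward_sa
#' @param delta discount factor in `[0, 1)`.
#' @return Length-4 numeric vector of state values.
#' @export
state_values <- function(game, x, agent, delta) {
  stopifnot(delta >= 0, delta < 1)
  p <- avg_transition_joint(game, x)
  r <- avg_state_reward(game, x, agent)
  v <- solve(diag(4) - delta * p, r)
  stats::setNames(as.numeric(v), game$states)
}

#' Strategy-average state-action qualities
#'
#' `qbar_i(s, a) = rbar_i(s, a) + delta * sum_{s'} pbar_i(s' | a, s) v_i(s')`:
#' the expected discounted return from playing `a` in `s` and then following
#' the joint strategy.
#'
#' @inheritParams state_values
#' @return A 4 x 2 matrix.
#' @export
avg_quality <- function(game, x, agent, delta) {
  v <- state_values(game, x, agent, delta)
  p <- avg_transition_agent(game, x, agent)
  r <- avg_reward_sa(game, x, agent)
  q <- r
  for (s in 1:4) for (a in 1:2) q[s, a] <- r[s, a] + delta * sum(p[s, a, ] * v)
  q
}

#' Strategy-average expected value of the next state
#'
#' `nextq_i(s, a)`: expectation, over the co-player's action and the induced
#' next state `s'`, of the own-strategy average of the strategy-average
#' qualities `qbar_i(s', .)`. Despite being a next-state expectation it
#' depends on both `s` and `a` through the transition.
#'
#' @inheritParams state_values
#' @return A 4 x 2 matrix.
#' @export
next_state_value <- function(game, x, agent, delta) {
  qbar <- avg_quality(game, x, agent, delta)
  p <- avg_transition_agent(game, x, agent)
  vq <- rowSums(x[[agent]] * qbar)  # own-strategy average of qbar at each s'
  out <- value_table(0)
  for (s in 1:4) for (a in 1:2) out[s, a] <- sum(p[s, a, ] * vq)
  out
}

#' One step of the deterministic strategy-average dynamics
#'
#' Updates every entry of both agents' value tables simultaneously:
#' `q <- q + alpha * (rbar(s, a) + delta * nextq(s, a) - q)`,
#' with all strategy averages taken under the joint epsilon-greedy strategy
#' induced by the *incoming* value tables.
#'
#' @param q_list list of two value tables.
#' @param game an [ipd_game()].
#' @param params a [learner_params()].
#' @return The updated list of two value tables.
#' @export
det_update <- function(q_list, game, params) {
  q_list <- lapply(q_list, as_value_table)
  x <- joint_frequencies(q_list, params$epsilon)
  lapply(1:2, function(i) {
    target <- avg_reward_sa(game, x, i) +
      params$delta * next_state_value(game, x, i, params$delta)
    q_list[[i]] + params$alpha * (target - q_list[[i]])
  })
}

#' Iterate the deterministic dynamics to convergence and classify
#'
#' Iterates [det_update()] from `q0` until the maximum absolute value change
#' stays below `tol` *and* the greedy strategy pair is unchanged for `window`
#' consecutive iterations, or until `max_iters`. The final greedy pair is
#' classified regardless; non-convergence within the iteration budget is a
#' labelled outcome, not an error (the greedy pair typically stabilises long
#' before the values meet a tight tolerance).
#'
#' @param q0 list of two initial value tables.
#' @param game an [ipd_game()].
#' @param params a [learner_params()].
#' @param tol max-norm tolerance on the per-iteration value change.
#' @param max_iters iteration cap.
#' @param window number of consecutive qualifying iterations required.
#' @param use_cpp iterate in compiled code (default) or in R (reference path).
#' @return List with `label` (`"AllD"`, `"GT"`, `"WSLS"`, `"other"`),
#'   `converged`, `iterations`, and the final `q` list.
#' @export
converge_and_classify <- function(q0, game, params, tol = 1e-8,
                                  max_iters = 1e5, window = 100,
                                  use_cpp = TRUE) {
  stopifnot(tol > 0, max_iters >= 1, window >= 1)
  q0 <- lapply(q0, as_value_table)
  if (use_cpp) {
    res <- cpp_converge_classify(q0[[1]], q0[[2]], game$T, game$S,
                                 params$alpha, params$epsilon, params$delta,
                                 tol, as.integer(max_iters), as.integer(window))
    qf <- list(value_table(res$q1), value_table(res$q2))
    return(list(label = classify_pair(res$code), converged = res$converged,
                iterations = res$iterations, q = qf))
  }
  q <- q0
  streak <- 0L
  prev_code <- pair_index(strategy_pair(greedy_strategy(q[[1]]),
                                        greedy_strategy(q[[2]])))
  for (it in seq_len(max_iters)) {
    q_new <- det_update(q, game, params)
    dmax <- max(abs(q_new[[1]] - q[[1]]), abs(q_new[[2]] - q[[2]]))
    code <- pair_index(strategy_pair(greedy_strategy(q_new[[1]]),
                                     greedy_strategy(q_new[[2]])))
    streak <- if (dmax < tol && code == prev_code) streak + 1L else 0L
    prev_code <- code
    q <- q_new
    if (streak >= window)
      return(list(label = classify_pair(code), converged = TRUE,
                  iterations = it, q = q))
  }
  list(label = classify_pair(prev_code), converged = FALSE,
       iterations = max_iters, q = q)
}

#' Basin fractions of the deterministic dynamics over random initial values
#'
#' Draws `n_inits` pairs of initial value tables i.i.d. uniform on
#' `[S/(1-delta), T/(1-delta)]` (per entry, per agent), iterates the
#' deterministic dynamics from each, and tabulates the fractions of runs
#' that converge with final greedy pair AllD, GT or WSLS, with Wilson 95%
#' intervals. The `other` row collects the remainder: converged runs at an
#' unnamed pair together with runs that never met the convergence criterion
#' (the dynamics can settle on value-space limit cycles, e.g. hovering
#' around an ordering boundary of an unstable pattern).
#'
#' @param game an [ipd_game()].
#' @param alpha,epsilon,delta learner parameters.
#' @param n_inits number of random initial joint value tables.
#' @param seed integer seed for the draws.
#' @param init_range optional override of the uniform initialisation range.
#' @param ... passed to [converge_and_classify()].
#' @return A data frame with one row per label: `label`, `fraction`, `lower`,
#'   `upper`, `n`, plus an attribute `n_converged`.
#' @export
basin_fractions <- function(game, alpha, epsilon, delta, n_inits = 250,
                            seed = 1L, init_range = NULL, ...) {
  params <- learner_params(alpha, epsilon, delta)
  labels <- withr_seed(seed, {
    inits1 <- random_value_tables(game, delta, n_inits, range = init_range)
    inits2 <- random_value_tables(game, delta, n_inits, range = init_range)
    res <- mapply(function(qa, qb) {
      out <- converge_and_classify(list(qa, qb), game, params, ...)
      c(out$label, out$converged)
    }, inits1, inits2)
    res
  })
  lab <- labels[1, ]
  lab[labels[2, ] != "TRUE"] <- "other"  # non-converged runs are unresolved
  out <- do.call(rbind, lapply(c("AllD", "GT", "WSLS", "other"), function(L) {
    k <- sum(lab == L)
    ci <- wilson_interval(k, n_inits)
    data.frame(label = L, fraction = k / n_inits,
               lower = ci$lower, upper = ci$upper, n = n_inits)
  }))
  attr(out, "n_converged") <- sum(labels[2, ] == "TRUE")
  out
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' WSLS learnability over a learning-rate / exploration-rate grid
#'
#' Runs [basin_fractions()] at every `(alpha, epsilon)` combination and
#' returns the per-label fractions in long format — the data behind a
#' learnability phase plot.
#'
#' @param game an [ipd_game()].
#' @param alpha_grid,epsilon_grid non-empty numeric grids.
#' @param delta discount factor.
#' @param n_inits,seed as in [basin_fractions()].
#' @param ... passed to [converge_and_classify()].
#' @return A data frame with columns `alpha`, `epsilon`, `frac_wsls`,
#'   `frac_gt`, `frac_alld`, `frac_other`.
#' @export
learnability_grid <- function(game, alpha_grid, epsilon_grid, delta = 0.99,
                              n_inits = 250, seed = 1L, ...) {
  grid <- expand.grid(alpha = alpha_grid, epsilon = epsilon_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    bf <- basin_fractions(game, grid$alpha[r], grid$epsilon[r], delta,
                          n_inits = n_inits, seed = seed, ...)
    frac <- stats::setNames(bf$fraction, bf$label)
    data.frame(alpha = grid$alpha[r], epsilon = grid$epsilon[r],
               frac_wsls = frac[["WSLS"]], frac_gt = frac[["GT"]],
               frac_alld = frac[["AllD"]], frac_other = frac[["other"]])
  })
  do.call(rbind, rows)
}
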