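#' Sample-batch Expected SARSA
#'
#' The batch variant alternates an *interaction phase* — `K` steps played with
#' a frozen epsilon-greedy strategy while temporal-difference targets are
#' averaged into a valuation table — and an *adaptation phase* — one update of
#' the acting values with a global learning rate. The batch size `K`
#' interpolates between fully online learning (`K = 1`) and the deterministic
#' strategy-average dynamics (`K -> Inf`).
#'
#' @name batch_learning
NULL

#' Local learning rate of the valuation table
#'
#' The valuation table is updated with rate `1/(t + 1)`, where `t` counts
#' previous updates of that `(s, a)` entry within the current batch; this
#' makes the entry the arithmetic mean of its sampled targets, so every sample
#' in the batch is valued equally.
#'
#' @param t non-negative integer count of previous within-batch updates.
#' @return `1 / (t + 1)`.
#' @export
local_rate <- function(t) {
  stopifnot(all(t >= 0))
  1 / (t + 1)
}

#' Constructor for one agent's batch-learner state
#'
#' @param q_act acting value table (frozen during an interaction phase).
#' @param K batch size (positive integer).
#' @return A `batch_learner_state`: list with acting values `q_act`,
#'   valuation values `q_val` (warm-started at `q_act`), per-entry update
#'   counters `counts`, and `K`.
#' @export
batch_learner_state <- function(q_act, K) {
  q_act <- as_value_table(q_act)
  stopifnot(K >= 1)
  structure(list(q_act = q_act, q_val = q_act,
                 counts = value_table(0), K = as.integer(K)),
            class = "batch_learner_state")
}

#' Interaction phase: play K steps with frozen strategies
#'
#' Both agents act with the fixed epsilon-greedy strategies derived from
#' their acting tables. For every visited `(s, a)` the valuation table
#' receives the sampled target `r + delta * sum_b x_act(b | s') q_val(s', b)`
#' at the local rate `1/(t+1)` — the action frequencies are frozen at the
#' acting strategy, while the bootstrap uses the evolving valuation table,
#' so the within-batch recursion performs value iteration for the frozen
#' strategy and the infinite-batch limit of the adaptation step is exactly
#' the deterministic strategy-average update. Consumes the current R RNG
#' stream.
#'
#' @param agents list of two [batch_learner_state()] objects (counters zero,
#'   `q_val` warm-started), one per agent.
#' @param game an [ipd_game()].
#' @param params a [learner_params()] (`alpha` unused here).
#' @param start_state state label at which the batch begins.
#' @return List with updated `agents` and the `end_state` label.
#' @export
interaction_phase <- function(agents, game, params, start_state) {
  stopifnot(length(agents) == 2L,
            all(vapply(agents, inherits, TRUE, "batch_learner_state")))
  K <- agents[[1]]$K
  stopifnot(agents[[2]]$K == K)
  eps <- params$epsilon; delta <- params$delta
  pure <- lapply(agents, function(b) greedy_strategy(b$q_act))
  x_act <- lapply(pure, action_frequencies, epsilon = eps)
  s <- match_state(game, start_state)
  for (step in seq_len(K)) {
    a <- vapply(1:2, function(i) {
      if (stats::runif(1) < eps) sample(1:2, 1) else match(pure[[i]][s], ACTIONS)
    }, integer(1))
    s_next <- joint_to_state(a[1], a[2])
    for (i in 1:2) {
      v_next <- sum(x_act[[i]][s_next, ] * agents[[i]]$q_val[s_next, ])
      target <- game$reward_next[i, s_next] + delta * v_next
      t_sa <- agents[[i]]$counts[s, a[i]]
      rate <- local_rate(t_sa)
      agents[[i]]$q_val[s, a[i]] <-
        (1 - rate) * agents[[i]]$q_val[s, a[i]] + rate * target
      agents[[i]]$counts[s, a[i]] <- t_sa + 1
    }
    s <- s_next
  }
  list(agents = agents, end_state = game$states[s])
}

#' Adaptation phase: fold the batch estimate into the acting values
#'
#' Every `(s, a)` visited at least once in the batch moves toward its batch
#' mean target: `q_act(s,a) <- (1 - alpha) q_act(s,a) + alpha * q_val(s,a)`.
#' Unvisited entries are unchanged. Counters reset and the valuation table is
#' re-initialised to the new acting values for the next batch.
#'
#' @param state a [batch_learner_state()] after an interaction phase.
#' @param alpha global learning rate in `[0, 1]`.
#' @return The updated `batch_learner_state`.
#' @export
adaptation_phase <- function(state, alpha) {
  stopifnot(inherits(state, "batch_learner_state"),
            alpha >= 0, alpha <= 1)
  visited <- state$counts > 0
  state$q_act[visited] <- (1 - alpha) * state$q_act[visited] +
    alpha * state$q_val[visited]
  state$counts[] <- 0
  state$q_val <- state$q_act
  state
}

#' Simulate sample-batch Expected SARSA self-play
#'
#' Runs `floor(horizon / K)` alternating interaction/adaptation cycles per
#' trajectory for `n_samples` independent trajectories; both agents share
#' batch boundaries and the environment state carries over across them.
#' Greedy strategy pairs of the acting tables are classified at recorded
#' batch boundaries against cumulative environment time, with Wilson 95%
#' intervals attached; `coop_rate` is the fraction of mutual-cooperation
#' states within the last batch. Initialisation and seeding are as in
#' [run_online()].
#'
#' @inheritParams run_online
#' @param K batch size (steps per interaction phase).
#' @param record_every_batches recording cadence in batches.
#' @return A `run_summary` (see [run_online()]).
#' @export
run_batch <- function(game, params, K, horizon, n_samples,
                      record_every_batches = 1L, init = NULL,
                      init_range = NULL, seed = 1L) {
  stopifnot(inherits(game, "ipd_game"), inherits(params, "learner_params"),
            K >= 1, horizon >= K, n_samples >= 1)
  n_batches <- as.integer(horizon %/% K)
  rng <- init_matrices(game, params$delta, init, init_range)
  res <- cpp_run_batch(game$T, game$S, params$alpha, params$epsilon,
                       params$delta, as.integer(K), n_batches,
                       as.integer(record_every_batches),
                       as.integer(n_samples), as.integer(seed),
                       rng$lo, rng$hi, rng$q1, rng$q2, rng$state0)
  new_run_summary(res, game, params, n_samples, seed,
                  algorithm = "batch",
                  extra = list(K = K, horizon = n_batches * as.integer(K)))
}

#' Robustness sweep over batch-learning parameters
#'
#' For every combination of batch size, learning rate and exploration rate,
#' runs [run_batch()] and records the final WSLS trajectory fraction and the
#' first time (environment steps) at which that fraction reaches `threshold`
#' (`NA` if it never does).
#'
#' @param game an [ipd_game()] (or a list of them, swept over).
#' @param K_grid,alpha_grid,epsilon_grid non-empty numeric grids.
#' @param delta discount factor shared across the sweep.
#' @param horizon,n_samples,seed as in [run_batch()].
#' @param threshold WSLS fraction defining the reach time.
#' @return A data frame with one row per combination: `T`, `S`, `K`, `alpha`,
#'   `epsilon`, `final_wsls_frac`, `wsls_lo`, `wsls_hi`, `reach_time_steps`.
#' @export
robustness_sweep <- function(game, K_grid, alpha_grid, epsilon_grid,
                             delta = 0.99, horizon = 2e6, n_samples = 100,
                             threshold = 0.4, seed = 1L) {
  stopifnot(length(K_grid) > 0, length(alpha_grid) > 0, length(epsilon_grid) > 0)
  games <- if (inherits(game, "ipd_game")) list(game) else game
  grid <- expand.grid(gi = seq_along(games), K = K_grid, alpha = alpha_grid,
                      epsilon = epsilon_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- games[[grid$gi[r]]]
    pars <- learner_params(grid$alpha[r], grid$epsilon[r], delta)
    sm <- run_batch(g, pars, K = grid$K[r], horizon = horizon,
                    n_samples = n_samples, seed = seed)
    last <- sm$series[nrow(sm$series), ]
    data.frame(T = g$T, S = g$S, K = grid$K[r], alpha = grid$alpha[r],
               epsilon = grid$epsilon[r], final_wsls_frac = last$frac_wsls,
               wsls_lo = last$wsls_lo, wsls_hi = last$wsls_hi,
               reach_time_steps = reach_time(sm, threshold))
  })
  do.call(rbind, rows)
}
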