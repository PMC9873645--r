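#' One Expected SARSA update of a value table
#'
#' Applies the tabular Expected SARSA rule to a single entry:
#' `q(s, a) <- (1 - alpha) q(s, a) + alpha [r + delta * sum_b x(b | s') q(s', b)]`.
#' The bootstrap term is the expectation of the next-state values under the
#' agent's *own* current epsilon-greedy action frequencies `x`; all other
#' entries are untouched.
#'
#' @param q a 4 x 2 value table.
#' @param s,s_next state labels (current and next).
#' @param a action label taken in `s`.
#' @param r numeric reward received.
#' @param x the agent's current 4 x 2 action-frequency table (rows sum to 1).
#' @param params a [learner_params()].
#' @return The updated value table.
#' @export
td_update <- function(q, s, a, r, s_next, x, params) {
  q <- as_value_table(q)
  stopifnot(inherits(params, "learner_params"), is.numeric(r), is.finite(r))
  si <- match(s, STATES); sj <- match(s_next, STATES); ai <- match(a, ACTIONS)
  if (is.na(si) || is.na(sj)) stop("invalid state label")
  if (is.na(ai)) stop("invalid action label")
  v_next <- sum(x[sj, ] * q[sj, ])
  q[si, ai] <- (1 - params$alpha) * q[si, ai] +
    params$alpha * (r + params$delta * v_next)
  q
}

#' Simulate fully online Expected SARSA self-play
#'
#' Runs `n_samples` independent two-agent trajectories of epsilon-greedy
#' Expected SARSA in the memory-one iterated Prisoner's Dilemma. Both agents
#' update synchronously from the shared transition each step. At each recorded
#' time the current greedy strategy pair of every trajectory is classified
#' (AllD / GT / WSLS / other) and the mutual-cooperation rate over the
#' trailing `coop_window` steps is measured.
#'
#' Unless `init` is given, each trajectory draws its initial state-action
#' values i.i.d. uniform on `[S/(1-delta), T/(1-delta)]` (the feasible range
#' of discounted returns) and its initial state uniformly over the four
#' states, from a per-trajectory random substream derived from `seed` — so
#' enlarging `n_samples` leaves earlier trajectories unchanged.
#'
#' @param game an [ipd_game()].
#' @param params a [learner_params()].
#' @param horizon number of environment time steps per trajectory.
#' @param n_samples number of independent trajectories.
#' @param record_every recording cadence in steps.
#' @param coop_window trailing window (steps) for the cooperation rate.
#' @param init optional fixed initialisation applied to every trajectory: a
#'   list with value tables `q1` and `q2` (and optionally a `state` label).
#' @param init_range optional length-2 numeric overriding the uniform
#'   initialisation range.
#' @param seed integer seed; runs are exactly reproducible from it.
#' @return A `run_summary`: list with a data frame `series` (columns `time`,
#'   per-equilibrium fractions with Wilson 95% bounds, `coop_rate`), the raw
#'   per-trajectory pair codes, the final value tables of every trajectory
#'   (`final_q`, one `n_samples` x 8 matrix per agent), and run metadata.
#' @export
run_online <- function(game, params, horizon, n_samples,
                       record_every = 1000L, coop_window = 1000L,
                       init = NULL, init_range = NULL, seed = 1L) {
  stopifnot(inherits(game, "ipd_game"), inherits(params, "learner_params"),
            horizon >= 1, n_samples >= 1)
  rng <- init_matrices(game, params$delta, init, init_range)
  res <- cpp_run_online(game$T, game$S, params$alpha, params$epsilon,
                        params$delta, as.integer(horizon),
                        as.integer(record_every), as.integer(coop_window),
                        as.integer(n_samples), as.integer(seed),
                        rng$lo, rng$hi, rng$q1, rng$q2, rng$state0)
  new_run_summary(res, game, params, n_samples, seed,
                  algorithm = "online", extra = list(horizon = horizon))
}

# resolve the initialisation spec shared by run_online and run_batch
init_matrices <- function(game, delta, init, init_range) {
  if (is.null(init_range)) init_range <- c(game$S, game$T) / (1 - delta)
  stopifnot(length(init_range) == 2L, init_range[1] < init_range[2])
  if (is.null(init))
    return(list(lo = init_range[1], hi = init_range[2],
                q1 = NULL, q2 = NULL, state0 = -1L))
  q1 <- as_value_table(init$q1)
  q2 <- as_value_table(init$q2)
  state0 <- if (is.null(init$state)) -1L else match_state(game, init$state) - 1L
  list(lo = init_range[1], hi = init_range[2], q1 = q1, q2 = q2,
       state0 = as.integer(state0))
}

new_run_summary <- function(res, game, params, n_samples, seed, algorithm,
                            extra = list()) {
  codes <- res$codes
  times <- res$times
  labels <- c(AllD = pair_code("AllD"), GT = pair_code("GT"),
              WSLS = pair_code("WSLS"))
  frac <- vapply(labels, function(cd) rowMeans(codes == cd), numeric(nrow(codes)))
  wil <- lapply(names(labels), function(lb) {
    k <- round(frac[, lb] * n_samples)
    ci <- wilson_interval(k, n_samples)
    stats::setNames(data.frame(ci$lower, ci$upper),
                    paste0(tolower(lb), c("_lo", "_hi")))
  })
  series <- data.frame(time = times, n = n_samples,
                       frac_alld = frac[, "AllD"], frac_gt = frac[, "GT"],
                       frac_wsls = frac[, "WSLS"],
                       coop_rate = rowMeans(res$coop))
  series <- cbind(series, do.call(cbind, wil))
  qcols <- paste(rep(STATES, each = 2), rep(ACTIONS, 4), sep = ".")
  final_q <- stats::setNames(lapply(res[c("fq1", "fq2")], `colnames<-`, qcols),
                             c("q1", "q2"))
  structure(c(list(series = series, codes = codes, final_q = final_q,
                   n_samples = n_samples, seed = seed, game = game,
                   params = params, algorithm = algorithm), extra),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("run_summary (%s): %d trajectories, %d recorded times\n",
              x$algorithm, x$n_samples, nrow(x$series)))
  last <- x$series[nrow(x$series), ]
  cat(sprintf("  final t = %g: WSLS %.3f [%.3f, %.3f], GT %.3f, AllD %.3f, coop %.3f\n",
              last$time, last$frac_wsls, last$wsls_lo, last$wsls_hi,
              last$frac_gt, last$frac_alld, last$coop_rate))
  invisible(x)
}

#' First time a recorded equilibrium fraction reaches a threshold
#'
#' @param summary a `run_summary`.
#' @param threshold fraction in `[0, 1]`.
#' @param label which equilibrium fraction to track.
#' @return The first recorded time (environment steps) at which the fraction
#'   is `>= threshold`, or `NA` if it never is.
#' @export
reach_time <- function(summary, threshold = 0.4, label = "WSLS") {
  col <- paste0("frac_", tolower(label))
  hit <- which(summary$series[[col]] >= threshold)
  if (length(hit) == 0L) NA_real_ else summary$series$time[hit[1]]
}
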