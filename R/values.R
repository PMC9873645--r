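#' State-action value tables and learner parameters
#'
#' A value table holds one agent's quality estimates `q(s, a)` over the four
#' states and two actions. It is represented as a plain 4 x 2 numeric matrix
#' with states `(cc, cd, dc, dd)` in rows and actions `(c, d)` in columns.
#'
#' @param values a scalar (recycled), a length-8 vector in row-major state
#'   order, or a 4 x 2 matrix.
#' @return A 4 x 2 numeric matrix with canonical dimnames.
#' @export
value_table <- function(values = 0) {
  if (length(values) == 1L) values <- rep(values, 8L)
  if (is.matrix(values)) {
    stopifnot(identical(dim(values), c(4L, 2L)))
    q <- values
  } else {
    stopifnot(length(values) == 8L)
    q <- matrix(values, nrow = 4, ncol = 2, byrow = TRUE)
  }
  dimnames(q) <- list(state = STATES, action = ACTIONS)
  storage.mode(q) <- "double"
  q
}

as_value_table <- function(q) {
  if (!is.numeric(q) || !is.matrix(q) || !identical(dim(q), c(4L, 2L)))
    stop("a value table is a 4 x 2 numeric matrix (states x actions)")
  if (!all(is.finite(q))) stop("value table entries must be finite")
  dimnames(q) <- list(state = STATES, action = ACTIONS)
  q
}

#' A value table whose greedy strategy is a given pure strategy
#'
#' Convenience for seeding learners at a strategy: the greedy action gets
#' value `high` and the other `low` in every state.
#'
#' @param pure a pure strategy.
#' @param high,low values for the greedy and non-greedy action.
#' @return A 4 x 2 value table.
#' @export
value_table_for_strategy <- function(pure, high = 1, low = 0) {
  check_pure(pure)
  stopifnot(high > low)
  q <- value_table(low)
  q[cbind(1:4, match(pure, ACTIONS))] <- high
  q
}

#' Learner parameters for temporal-difference learning
#'
#' @param alpha learning rate in `[0, 1]`: weight of the sampled
#'   temporal-difference target in each update.
#' @param epsilon exploration rate in `[0, 1)`: probability of choosing an
#'   action uniformly at random instead of the greedy one.
#' @param delta discount factor in `[0, 1)`: weight on future rewards.
#' @return An object of class `learner_params`.
#' @export
learner_params <- function(alpha = 0.1, epsilon = 0.01, delta = 0.98) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)")
  check_epsilon(epsilon)
  structure(list(alpha = alpha, epsilon = epsilon, delta = delta),
            class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf("learner_params: alpha = %g, epsilon = %g, delta = %g\n",
              x$alpha, x$epsilon, x$delta))
  invisible(x)
}

#' Random initial value tables
#'
#' Draws i.i.d. uniform initial state-action values on the feasible range of
#' discounted returns, `[S/(1-delta), T/(1-delta)]` — the default
#' initialisation shared by the online, batch and deterministic processes so
#' basin estimates are comparable across them. Uses the current R RNG state.
#'
#' @param game an [ipd_game()].
#' @param delta discount factor.
#' @param n number of tables to draw.
#' @param range optional length-2 numeric overriding the default range.
#' @return A list of `n` value tables.
#' @export
random_value_tables <- function(game, delta, n = 1, range = NULL) {
  if (is.null(range)) range <- c(game$S, game$T) / (1 - delta)
  stopifnot(length(range) == 2L, range[1] < range[2])
  lapply(seq_len(n), function(i)
    value_table(stats::runif(8, range[1], range[2])))
}
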