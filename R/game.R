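#' The memory-one iterated Prisoner's Dilemma environment
#'
#' Constructs the repeated 2x2 social dilemma with one-period memory. The
#' environmental state is the joint action of the previous round, so the state
#' set is `{cc, cd, dc, dd}` (agent 1's previous action first) and the
#' transition kernel is deterministic: the next state *is* the joint action
#' just played. Payoffs are normalised so mutual cooperation yields 1 and
#' mutual defection 0; the temptation payoff `T > 1` and the sucker payoff
#' `S < 0` parameterise the dilemma.
#'
#' @param T temptation payoff to a defector facing a cooperator; must exceed 1.
#' @param S sucker payoff to a cooperator facing a defector; must be negative.
#'
#' @return An object of class `ipd_game`: a list with elements `T`, `S`,
#'   `states` (the four state labels in canonical order), `actions`
#'   (`c("c", "d")`), and `reward_next` — a 2 x 4 matrix giving each agent's
#'   payoff as a function of the *next* state (equivalently, of the joint
#'   action played).
#'
#' @examples
#' g <- ipd_game(T = 1.5, S = -0.2)
#' reward(g, 1, c("c", "d"))   # sucker payoff S
#' transition(g, "cc", c("d", "c"))
#' @export
ipd_game <- function(T = 1.5, S = -0.2) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T),
            is.numeric(S), length(S) == 1L, is.finite(S))
  if (T <= 1) stop("temptation payoff T must exceed 1 (dilemma condition T > 1 > 0 > S)")
  if (S >= 0) stop("sucker payoff S must be negative (dilemma condition T > 1 > 0 > S)")
  states <- c("cc", "cd", "dc", "dd")
  actions <- c("c", "d")
  # payoff as a function of the state just entered (== joint action played):
  # agent 1 row: (c,c)->1, (c,d)->S, (d,c)->T, (d,d)->0; agent 2 mirrored.
  reward_next <- rbind(c(1, S, T, 0),
                       c(1, T, S, 0))
  dimnames(reward_next) <- list(agent = c("1", "2"), state = states)
  structure(list(T = T, S = S, states = states, actions = actions,
                 reward_next = reward_next),
            class = "ipd_game")
}

#' @export
print.ipd_game <- function(x, ...) {
  cat("Iterated Prisoner's Dilemma (memory-one)\n")
  cat(sprintf("  payoffs: R = 1, P = 0, T = %g, S = %g\n", x$T, x$S))
  cat("  states:", paste(x$states, collapse = " "), " actions:",
      paste(x$actions, collapse = " "), "\n")
  invisible(x)
}

match_state <- function(game, state) {
  i <- match(state, game$states)
  if (anyNA(i)) stop("invalid state label: ", paste(state[is.na(i)], collapse = ", "))
  i
}

match_action <- function(game, action) {
  i <- match(action, game$actions)
  if (anyNA(i)) stop("invalid action label: ", paste(action[is.na(i)], collapse = ", "))
  i
}

#' State transition of the memory-one environment
#'
#' The next state signals the joint action of the round just played; it does
#' not depend on the incoming state.
#'
#' @param game an [ipd_game()].
#' @param state current state label (validated, otherwise unused).
#' @param joint_action character vector of length 2: agent 1's and agent 2's
#'   action, each `"c"` or `"d"`.
#' @return The next state label.
#' @export
transition <- function(game, state, joint_action) {
  match_state(game, state)
  a <- match_action(game, joint_action)
  stopifnot(length(a) == 2L)
  game$states[joint_to_state(a[1], a[2])]
}

# joint action (1 = c, 2 = d per agent) -> state index in (cc, cd, dc, dd)
joint_to_state <- function(a1, a2) 2L * (a1 - 1L) + (a2 - 1L) + 1L

#' Payoff of one agent for a joint action
#'
#' @inheritParams transition
#' @param agent 1 or 2.
#' @return Numeric payoff: agent 1 receives `1, S, T, 0` for joint actions
#'   `(c,c), (c,d), (d,c), (d,d)`; agent 2 has `S` and `T` swapped.
#' @export
reward <- function(game, agent, joint_action) {
  if (!agent %in% c(1, 2)) stop("agent must be 1 or 2")
  a <- match_action(game, joint_action)
  stopifnot(length(a) == 2L)
  game$reward_next[agent, joint_to_state(a[1], a[2])]
}

#' Materialised transition kernel p(s' | a1, a2, s)
#'
#' Returns the full (degenerate) kernel of the memory-one environment as a
#' 4-dimensional array indexed `[s, a1, a2, s']`. Every row over `s'` sums to
#' one and puts all mass on the state labelled by the joint action. The array
#' form exists so that the strategy-average dynamics and best-response code
#' paths are written against a general stochastic kernel.
#'
#' @inheritParams transition
#' @return A `4 x 2 x 2 x 4` numeric array with dimnames
#'   `(s, a1, a2, s_next)`.
#' @export
transition_kernel <- function(game) {
  p <- array(0, dim = c(4, 2, 2, 4),
             dimnames = list(s = game$states, a1 = game$actions,
                             a2 = game$actions, s_next = game$states))
  for (a1 in 1:2) for (a2 in 1:2) p[, a1, a2, joint_to_state(a1, a2)] <- 1
  p
}
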