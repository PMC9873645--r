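#' Mutual best-response networks over the 256 strategy pairs
#'
#' Fixing the opponent's epsilon-greedy strategy induces a four-state Markov
#' decision process for the focal agent; solving its Bellman equations (under
#' forced epsilon-exploration) yields the epsilon-greedy best response. The
#' mutual best-response map sends each of the 256 strategy pairs to the pair
#' of best responses to the respective opponents; its functional graph is the
#' mutual best-response network (MBRN). Self-loops are the equilibria of
#' learning, and the fraction of pairs whose orbit reaches an equilibrium is
#' its basin of attraction.
#'
#' @name mbrn
NULL

#' Epsilon-greedy best response to a fixed opponent strategy
#'
#' Computes the unique fixed point of the epsilon-greedy Bellman optimality
#' operator
#' `q*(s,a) = rbar(s,a) + delta * sum_{s'} pbar(s'|a,s) [(1-eps) max_b q*(s',b) + (eps/2) sum_b q*(s',b)]`
#' for the single-agent MDP induced by the opponent's epsilon-greedy
#' strategy, by policy iteration with exact (matrix-inversion) evaluation of
#' each candidate epsilon-greedy policy. The greedy strategy of `q*` is
#' returned under the shared defect-on-tie rule.
#'
#' @param game an [ipd_game()].
#' @param opponent the opponent's pure strategy (length-4 character vector).
#' @param epsilon exploration rate of *both* strategies.
#' @param delta discount factor in `[0, 1)`.
#' @param agent which seat the focal agent occupies (1 or 2); the opponent
#'   occupies the other.
#' @return The best-response pure strategy, with the fixed-point value table
#'   attached as attribute `"q"`.
#' @export
best_response <- function(game, opponent, epsilon, delta, agent = 1L) {
  check_pure(opponent); check_epsilon(epsilon)
  stopifnot(delta >= 0, delta < 1, agent %in% c(1L, 2L))
  x <- vector("list", 2)
  x[[3L - agent]] <- action_frequencies(opponent, epsilon)
  x[[agent]] <- matrix(0.5, 4, 2)  # placeholder; unused by the two calls below
  rbar <- avg_reward_sa(game, x, agent)
  pbar <- avg_transition_agent(game, x, agent)
  g <- STRAT_ALLD
  seen <- character(0)
  for (it in seq_len(32L)) {
    xg <- action_frequencies(g, epsilon)
    Pg <- matrix(0, 4, 4)
    for (s in 1:4) Pg[s, ] <- xg[s, 1] * pbar[s, 1, ] + xg[s, 2] * pbar[s, 2, ]
    rg <- rowSums(xg * rbar)
    v <- solve(diag(4) - delta * Pg, rg)
    q <- rbar
    for (s in 1:4) for (a in 1:2) q[s, a] <- rbar[s, a] + delta * sum(pbar[s, a, ] * v)
    g_new <- greedy_strategy(q)
    if (identical(unname(g_new), unname(g)) ||
        paste(g_new, collapse = "") %in% seen) {
      g <- g_new
      attr(g, "q") <- q
      return(g)
    }
    seen <- c(seen, paste(g, collapse = ""))
    g <- g_new
  }
  stop("policy iteration failed to settle within 32 improvements")
}

#' Enumeration oracle for the epsilon-greedy best response
#'
#' Evaluates all 16 candidate epsilon-greedy strategies against the fixed
#' opponent by exact policy evaluation and reports which candidates attain
#' the componentwise-maximal state-value vector (for an MDP, the optimal
#' policy maximises the value in every state simultaneously). Retained as an
#' independent cross-check of [best_response()].
#'
#' @inheritParams best_response
#' @return List with `values` (16 x 4 matrix of state values, rows named by
#'   the strategy strings) and `optimal` (indices 0..15 of the candidates
#'   within `1e-9` of the componentwise maximum).
#' @export
best_response_enum <- function(game, opponent, epsilon, delta, agent = 1L) {
  check_pure(opponent); check_epsilon(epsilon)
  stopifnot(delta >= 0, delta < 1, agent %in% c(1L, 2L))
  x <- vector("list", 2)
  x[[3L - agent]] <- action_frequencies(opponent, epsilon)
  values <- matrix(NA_real_, 16, 4,
                   dimnames = list(NULL, STATES))
  strings <- character(16)
  for (k in 0:15) {
    g <- strategy_from_index(k)
    x[[agent]] <- action_frequencies(g, epsilon)
    values[k + 1, ] <- state_values(game, x, agent, delta)
    strings[k + 1] <- paste(g, collapse = "")
  }
  rownames(values) <- strings
  vmax <- apply(values, 2, max)
  optimal <- which(apply(values, 1, function(v) all(v >= vmax - 1e-9))) - 1L
  list(values = values, optimal = optimal)
}

#' Build the mutual best-response network
#'
#' Applies [best_response()] in both seats to all 16 opponent strategies and
#' assembles the successor map on the 256 strategy pairs: the pair
#' `(s1, s2)` maps to `(BR_1(s2), BR_2(s1))`.
#'
#' @inheritParams best_response
#' @return An object of class `mbrn`: list with `successor` (integer vector
#'   of length 256; entry `code + 1` holds the successor's pair code),
#'   per-seat best-response tables `br1`, `br2` (length 16), and the
#'   parameter context.
#' @export
build_network <- function(game, epsilon, delta) {
  br1 <- vapply(0:15, function(k)
    strategy_index(best_response(game, strategy_from_index(k), epsilon, delta,
                                 agent = 1L)), integer(1))
  br2 <- vapply(0:15, function(k)
    strategy_index(best_response(game, strategy_from_index(k), epsilon, delta,
                                 agent = 2L)), integer(1))
  codes <- 0:255
  successor <- 16L * br1[codes %% 16L + 1L] + br2[codes %/% 16L + 1L]
  structure(list(successor = successor, br1 = br1, br2 = br2,
                 T = game$T, S = game$S, epsilon = epsilon, delta = delta),
            class = "mbrn")
}

#' @export
print.mbrn <- function(x, ...) {
  eq <- find_equilibria(x)
  cat(sprintf("mbrn: 256 strategy pairs at T = %g, S = %g, epsilon = %g, delta = %g\n",
              x$T, x$S, x$epsilon, x$delta))
  cat("  equilibria:", paste(sprintf("%s (%s)", eq$pair, eq$label), collapse = ", "), "\n")
  invisible(x)
}

#' Equilibria of a mutual best-response network
#'
#' Fixed points of the best-response map (self-loops). The AllD pair is one
#' at every parameter combination.
#'
#' @param net an [build_network()] result.
#' @return Data frame with columns `code`, `pair` (8-character string) and
#'   `label`.
#' @export
find_equilibria <- function(net) {
  stopifnot(inherits(net, "mbrn"))
  codes <- which(net$successor == 0:255) - 1L
  data.frame(code = codes,
             pair = vapply(codes, function(cd) pair_string(pair_from_index(cd)),
                           character(1)),
             label = vapply(codes, classify_pair, character(1)))
}

# successor map iterated 256 times (function-composition squaring); by then
# every orbit has entered its terminal cycle
orbit_endpoints <- function(net) {
  f <- net$successor + 1L  # 1-based
  for (k in 1:8) f <- f[f]
  f - 1L
}

#' Basin of attraction of an equilibrium pair
#'
#' Fraction of all 256 strategy pairs whose forward orbit under the mutual
#' best-response map reaches the given equilibrium — the probability of
#' ending there from a uniformly random initial pair.
#'
#' @param net an [build_network()] result.
#' @param pair an equilibrium strategy pair (list, 8-character string, or
#'   pair code 0..255); must be a fixed point of `net`.
#' @return The basin fraction in `[1/256, 1]`.
#' @export
basin_of_attraction <- function(net, pair) {
  stopifnot(inherits(net, "mbrn"))
  code <- if (is.numeric(pair)) as.integer(pair) else pair_index(as_strategy_pair(pair))
  if (net$successor[code + 1L] != code)
    stop("'pair' is not a fixed point of this network")
  mean(orbit_endpoints(net) == code)
}

#' Analytic stability threshold for the WSLS pair
#'
#' The symmetric Win-Stay Lose-Shift pair is an equilibrium of the mutual
#' best-response dynamics if and only if the discount factor exceeds
#' `(2(T-1) + eps(1-S-T)) / (2(1-eps)^2)`.
#'
#' @param T,S payoff parameters (`T > 1 > 0 > S`).
#' @param epsilon exploration rate in `[0, 1)`.
#' @return The critical discount factor (may exceed 1, meaning WSLS is never
#'   stable there).
#' @export
wsls_threshold <- function(T, S, epsilon) {
  check_epsilon(epsilon)
  (2 * (T - 1) + epsilon * (1 - S - T)) / (2 * (1 - epsilon)^2)
}

#' Analytic stability window for the GT pair
#'
#' The symmetric Grim Trigger pair is an equilibrium if and only if the
#' discount factor lies strictly between
#' `(2(T-1) + eps(1-S-T)) / ((1-eps)(2T - eps(S+T)))` and
#' `(2S + eps(1-S-T)) / ((1-eps)((2-eps)S - eps*T))`.
#'
#' @inheritParams wsls_threshold
#' @return Named numeric vector `c(lower, upper)`; entries are `NaN` when the
#'   corresponding denominator vanishes (boundary-degenerate parameters).
#' @export
gt_bounds <- function(T, S, epsilon) {
  check_epsilon(epsilon)
  lower_den <- (1 - epsilon) * (2 * T - epsilon * (S + T))
  upper_den <- (1 - epsilon) * ((2 - epsilon) * S - epsilon * T)
  c(lower = (2 * (T - 1) + epsilon * (1 - S - T)) / lower_den,
    upper = (2 * S + epsilon * (1 - S - T)) / upper_den)
}

#' Enumerative equilibrium check for the three named pairs
#'
#' Tests by direct best-response computation whether the symmetric AllD, GT
#' and WSLS pairs are self-loops of the mutual best-response map (a symmetric
#' pair is one iff both seats' best responses reproduce the strategy).
#'
#' @inheritParams build_network
#' @return Named logical vector over `AllD`, `GT`, `WSLS`.
#' @export
selfloop_equilibria <- function(game, epsilon, delta) {
  pats <- list(AllD = STRAT_ALLD, GT = STRAT_GT, WSLS = STRAT_WSLS)
  vapply(pats, function(p) {
    identical(unname(as.character(best_response(game, p, epsilon, delta, 1L))), p) &&
      identical(unname(as.character(best_response(game, p, epsilon, delta, 2L))), p)
  }, logical(1))
}

#' Analytic stability phase map over an exploration/discount grid
#'
#' Evaluates the closed-form stability conditions on a grid: AllD is stable
#' everywhere; GT inside its window; WSLS above its threshold.
#'
#' @param game an [ipd_game()].
#' @param epsilon_grid,delta_grid non-empty numeric grids.
#' @return Data frame with columns `epsilon`, `delta`, `alld_stable`,
#'   `gt_stable`, `wsls_stable`.
#' @export
phase_map <- function(game, epsilon_grid, delta_grid) {
  grid <- expand.grid(epsilon = epsilon_grid, delta = delta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  wt <- vapply(grid$epsilon, function(e) wsls_threshold(game$T, game$S, e),
               numeric(1))
  gb <- vapply(grid$epsilon, function(e) gt_bounds(game$T, game$S, e),
               numeric(2))
  data.frame(epsilon = grid$epsilon, delta = grid$delta,
             alld_stable = TRUE,
             gt_stable = grid$delta > gb["lower", ] & grid$delta < gb["upper", ],
             wsls_stable = grid$delta > wt)
}

#' Maximum WSLS basin of attraction over the parameter space
#'
#' Scans payoff, exploration and discount parameters, builds the mutual
#' best-response network at each point, and records the basin of attraction
#' of the WSLS pair (zero where it is not an equilibrium). Because the basin
#' is piecewise constant across network regions, the default grid is
#' augmented with discount values just above and below the analytic WSLS and
#' GT stability boundaries at each `(T, S, epsilon)`.
#'
#' @param T_grid,S_grid,epsilon_grid,delta_grid numeric grids; defaults cover
#'   `T` in (1, 3], `S` in [-1, 0), `epsilon` in [0, 0.5] and `delta` in
#'   [0, 0.999].
#' @param refine add boundary-straddling discount values from the analytic
#'   conditions (default `TRUE`).
#' @param offset half-width of the boundary straddle.
#' @return The maximum basin fraction, with attribute `"at"`: a data frame of
#'   the parameter points attaining it.
#' @export
max_wsls_basin <- function(T_grid = seq(1.2, 3, by = 0.2),
                           S_grid = seq(-1, -0.1, by = 0.1),
                           epsilon_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                           delta_grid = c(0.05, 0.3, 0.5, 0.7, 0.9, 0.99, 0.999),
                           refine = TRUE, offset = 0.005) {
  wsls_code <- pair_code("WSLS")
  best <- -1
  at <- list()
  for (Tp in T_grid) for (Sp in S_grid) {
    game <- ipd_game(Tp, Sp)
    for (eps in epsilon_grid) {
      deltas <- delta_grid
      if (refine) {
        marks <- c(wsls_threshold(Tp, Sp, eps), gt_bounds(Tp, Sp, eps))
        marks <- marks[is.finite(marks)]
        extra <- c(marks - offset, marks + offset)
        deltas <- sort(unique(c(deltas, extra[extra >= 0 & extra <= 0.999])))
      }
      for (delta in deltas) {
        net <- build_network(game, eps, delta)
        b <- if (net$successor[wsls_code + 1L] == wsls_code)
          basin_of_attraction(net, wsls_code) else 0
        if (b > best + 1e-12) {
          best <- b
          at <- list(data.frame(T = Tp, S = Sp, epsilon = eps, delta = delta,
                                basin = b))
        } else if (abs(b - best) <= 1e-12) {
          at <- c(at, list(data.frame(T = Tp, S = Sp, epsilon = eps,
                                      delta = delta, basin = b)))
        }
      }
    }
  }
  structure(best, at = utils::head(do.call(rbind, at), 50))
}
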