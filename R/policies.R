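#' @title Pure memory-one strategies and epsilon-greedy action frequencies
#' @name policies
#' @description
#' A pure memory-one strategy assigns one action to each of the four states
#' `(cc, cd, dc, dd)`; there are exactly 16 per agent and 256 joint strategy
#' pairs. An epsilon-greedy strategy plays the pure (greedy) action with
#' probability `1 - epsilon/2` per state and the other action with
#' probability `epsilon/2`.
NULL

STATES <- c("cc", "cd", "dc", "dd")
ACTIONS <- c("c", "d")

# canonical named pure strategies over (cc, cd, dc, dd)
STRAT_ALLD <- c("d", "d", "d", "d")
STRAT_GT <- c("c", "d", "d", "d")
STRAT_WSLS <- c("c", "d", "d", "c")

check_pure <- function(pure) {
  if (!is.character(pure) || length(pure) != 4L || !all(pure %in% ACTIONS))
    stop("a pure strategy is a length-4 character vector over {c, d} in state order (cc, cd, dc, dd)")
  invisible(pure)
}

#' Greedy pure strategy of a value table
#'
#' Extracts, per state, the action with the strictly largest state-action
#' value. Ties and `q(s, c) < q(s, d)` both yield defection: the two-branch
#' epsilon-greedy rule gives the high-probability branch to cooperation only
#' on strict inequality, so the "otherwise" branch (defect) absorbs ties.
#' This single tie rule is used everywhere in the package.
#'
#' @param q a 4 x 2 numeric value table (rows: states `cc, cd, dc, dd`;
#'   columns: actions `c, d`), all entries finite.
#' @return A pure strategy: character vector of length 4 over `{c, d}`.
#' @export
greedy_strategy <- function(q) {
  q <- as_value_table(q)
  ifelse(q[, 1] > q[, 2], "c", "d")
}

#' Epsilon-greedy action frequencies of a pure strategy
#'
#' @param pure a pure strategy (length-4 character vector over `{c, d}`).
#' @param epsilon exploration rate in `[0, 1)`.
#' @return A 4 x 2 matrix `x` with `x[s, a]` the probability of action `a`
#'   in state `s`: `1 - epsilon/2` for the greedy action, `epsilon/2` for the
#'   other. Rows sum to one.
#' @export
action_frequencies <- function(pure, epsilon) {
  check_pure(pure)
  check_epsilon(epsilon)
  x <- matrix(epsilon / 2, nrow = 4, ncol = 2,
              dimnames = list(state = STATES, action = ACTIONS))
  greedy_col <- match(pure, ACTIONS)
  x[cbind(1:4, greedy_col)] <- 1 - epsilon / 2
  x
}

check_epsilon <- function(epsilon) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)")
  invisible(epsilon)
}

#' Encode and decode pure strategies and strategy pairs
#'
#' Pure strategies are indexed 0..15 by reading the four per-state choices as
#' binary digits (defect = 1) over `(cc, cd, dc, dd)` with `cc` the most
#' significant bit; strategy pairs are indexed 0..255 as
#' `16 * index(agent 1) + index(agent 2)`. The string form concatenates agent
#' 1's four choices then agent 2's, e.g. `"cddccddc"` for the WSLS pair.
#'
#' @param pure a pure strategy; `index` an integer in 0..15 (`strategy_from_index`)
#'   or 0..255 (`pair_from_index`).
#' @return `strategy_index`/`pair_index` return integers; the `*_from_index`
#'   functions return a pure strategy / a strategy pair (list with elements
#'   `p1`, `p2`); `pair_string` returns an 8-character string.
#' @export
strategy_index <- function(pure) {
  check_pure(pure)
  sum((pure == "d") * c(8L, 4L, 2L, 1L))
}

#' @rdname strategy_index
#' @export
strategy_from_index <- function(index) {
  stopifnot(index %in% 0:15)
  bits <- as.integer(intToBits(index))[4:1]
  stats::setNames(ACTIONS[bits + 1L], STATES)
}

#' @rdname strategy_index
#' @param p1,p2 pure strategies of agents 1 and 2.
#' @export
strategy_pair <- function(p1, p2) {
  check_pure(p1); check_pure(p2)
  list(p1 = p1, p2 = p2)
}

#' @rdname strategy_index
#' @param pair a strategy pair (list with `p1`, `p2`) or 8-character string.
#' @export
pair_index <- function(pair) {
  pair <- as_strategy_pair(pair)
  16L * strategy_index(pair$p1) + strategy_index(pair$p2)
}

#' @rdname strategy_index
#' @export
pair_from_index <- function(index) {
  stopifnot(index %in% 0:255)
  strategy_pair(strategy_from_index(index %/% 16L), strategy_from_index(index %% 16L))
}

#' @rdname strategy_index
#' @export
pair_string <- function(pair) {
  pair <- as_strategy_pair(pair)
  paste0(paste(pair$p1, collapse = ""), paste(pair$p2, collapse = ""))
}

#' @rdname strategy_index
#' @export
as_strategy_pair <- function(pair) {
  if (is.character(pair) && length(pair) == 1L) {
    ch <- strsplit(pair, "")[[1]]
    if (length(ch) != 8L || !all(ch %in% ACTIONS))
      stop("a strategy-pair string has 8 characters over {c, d}")
    return(strategy_pair(ch[1:4], ch[5:8]))
  }
  if (is.list(pair) && all(c("p1", "p2") %in% names(pair)))
    return(strategy_pair(pair$p1, pair$p2))
  stop("cannot interpret 'pair' as a strategy pair")
}

#' Classify a strategy pair as AllD, GT, WSLS or other
#'
#' The three symmetric patterns are the only strategy-pair equilibria of
#' epsilon-greedy temporal-difference learning in this game (in the small
#' exploration limit): All-Defect (defect in every state), Grim Trigger
#' (cooperate only after mutual cooperation), and Win-Stay Lose-Shift
#' (cooperate after mutual cooperation or mutual defection). Both agents must
#' play the same pattern; every other pair — including Tit-for-Tat — is
#' `"other"`.
#'
#' @param pair a strategy pair (list with `p1`, `p2`, an 8-character string,
#'   or a pair index 0..255).
#' @return One of `"AllD"`, `"GT"`, `"WSLS"`, `"other"`.
#' @export
classify_pair <- function(pair) {
  if (is.numeric(pair) && length(pair) == 1L) pair <- pair_from_index(pair)
  pair <- as_strategy_pair(pair)
  if (!identical(unname(pair$p1), unname(pair$p2))) return("other")
  p <- unname(pair$p1)
  if (identical(p, STRAT_ALLD)) return("AllD")
  if (identical(p, STRAT_GT)) return("GT")
  if (identical(p, STRAT_WSLS)) return("WSLS")
  "other"
}

# pair indices of the named equilibria (used throughout)
pair_code <- function(label) {
  p <- switch(label,
    AllD = STRAT_ALLD, GT = STRAT_GT, WSLS = STRAT_WSLS,
    stop("unknown label"))
  16L * strategy_index(p) + strategy_index(p)
}
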