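# shared fixtures: the benchmark environment and the three named strategies
fig_game <- ipd_game(T = 1.5, S = -0.2)
alld <- c("d", "d", "d", "d")
gt <- c("c", "d", "d", "d")
wsls <- c("c", "d", "d", "c")

# strategy-average quality tables of a symmetric pure pair — used to seed
# dynamics tests at Bellman-consistent points
pair_qualities <- function(game, pure, epsilon, delta) {
  x <- list(action_frequencies(pure, epsilon),
            action_frequencies(pure, epsilon))
  lapply(1:2, function(i) avg_quality(game, x, i, delta))
}

expect_prob_rows <- function(m) {
  expect_true(all(m >= 0))
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)))
}
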