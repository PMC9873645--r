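test_that("the Expected SARSA update touches one entry with the right target", {
  p <- learner_params(alpha = 0.1, epsilon = 0.05, delta = 0.98)
  x <- action_frequencies(wsls, 0.05)
  q0 <- value_table(0)
  # alpha = 0 leaves the table unchanged
  p0 <- learner_params(alpha = 0, epsilon = 0.05, delta = 0.98)
  expect_equal(td_update(q0, "cc", "c", 1, "cc", x, p0), q0)
  # alpha = 1, delta = 0: the entry becomes the reward exactly
  p1 <- learner_params(alpha = 1, epsilon = 0.05, delta = 0)
  q <- td_update(q0, "cd", "d", 1.5, "dc", x, p1)
  expect_equal(q["cd", "d"], 1.5)
  expect_equal(sum(q != 0), 1)
  # zero table, alpha = 0.1, r = 1: entry becomes alpha * r
  q <- td_update(q0, "cc", "c", 1, "cc", x, p)
  expect_equal(q["cc", "c"], 0.1)
  expect_equal(sum(q != 0), 1)
  # bootstrap term weights next-state values by the supplied frequencies
  q1 <- value_table(cbind(rep(2, 4), rep(1, 4)))
  out <- td_update(q1, "dd", "d", 0, "cc", x, p)
  v <- sum(x["cc", ] * q1["cc", ])
  expect_equal(out["dd", "d"], (1 - 0.1) * 1 + 0.1 * (0 + 0.98 * v))
})

test_that("online runs are exactly reproducible and respect the init spec", {
  p <- learner_params(0.1, 0.05, 0.9)
  a <- run_online(fig_game, p, horizon = 2000, n_samples = 4, seed = 11)
  b <- run_online(fig_game, p, horizon = 2000, n_samples = 4, seed = 11)
  expect_identical(a$series, b$series)
  expect_identical(a$final_q, b$final_q)
  # enlarging the sample only appends trajectories
  c6 <- run_online(fig_game, p, horizon = 2000, n_samples = 6, seed = 11)
  expect_identical(c6$codes[, 1:4], a$codes)
  # fractions are proportions and the three named ones cannot exceed 1
  with(a$series, {
    expect_true(all(frac_alld >= 0 & frac_alld <= 1))
    expect_true(all(frac_alld + frac_gt + frac_wsls <= 1 + 1e-12))
  })
})

test_that("without exploration the named equilibria are absorbing", {
  for (pure in list(alld, gt, wsls)) {
    init <- list(q1 = value_table_for_strategy(pure, 1, 0),
                 q2 = value_table_for_strategy(pure, 1, 0),
                 state = "cc")
    p <- learner_params(alpha = 0.01, epsilon = 0, delta = 0.98)
    s <- run_online(fig_game, p, horizon = 1000, n_samples = 1,
                    record_every = 100, init = init, seed = 1)
    lab <- classify_pair(strategy_pair(pure, pure))
    expect_true(all(s$series[[paste0("frac_", tolower(lab))]] == 1))
  }
})

test_that("values stay inside the feasible discounted-return range", {
  # closure property of the update: targets r + delta * v lie in the range
  # spanned by min(S,0)/(1-delta) and max(T,1)/(1-delta)
  g <- fig_game
  delta <- 0.9
  lohi <- c(g$S, g$T) / (1 - delta)
  p <- learner_params(0.2, 0.1, delta)
  s <- run_online(g, p, horizon = 5000, n_samples = 10, seed = 21)
  for (m in s$final_q)
    expect_true(all(m >= lohi[1] - 1e-9 & m <= lohi[2] + 1e-9))
  # and as a pointwise property of td_update under random transitions
  set.seed(4)
  q <- value_table(stats::runif(8, lohi[1], lohi[2]))
  for (i in 1:200) {
    st <- sample(g$states, 1); a <- sample(g$actions, 2, replace = TRUE)
    sn <- transition(g, st, a)
    x <- action_frequencies(greedy_strategy(q), 0.1)
    q <- td_update(q, st, a[1], reward(g, 1, a), sn, x, p)
    expect_true(all(q >= lohi[1] & q <= lohi[2]))
  }
})

test_that("a trailing-window cooperation rate of one is reached under locked WSLS play", {
  # eps = 0, WSLS pair, start at cc: the play cycles on mutual cooperation
  init <- list(q1 = value_table_for_strategy(wsls, 1, 0),
               q2 = value_table_for_strategy(wsls, 1, 0),
               state = "cc")
  p <- learner_params(0.01, 0, 0.98)
  s <- run_online(fig_game, p, horizon = 2000, n_samples = 1,
                  record_every = 1000, init = init, seed = 1)
  expect_equal(s$series$coop_rate[-1], rep(1, 2))
})
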