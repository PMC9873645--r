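test_that("strategy-average rewards reduce to hand values for simple opponents", {
  g <- fig_game
  # opponent defects surely: cooperation earns S, defection earns 0, in all states
  x <- list(NULL, action_frequencies(alld, 0))
  r <- avg_reward_sa(g, x, 1)
  expect_equal(unname(r[, "c"]), rep(g$S, 4))
  expect_equal(unname(r[, "d"]), rep(0, 4))
  # uniform opponent: cooperation earns (1 + S)/2, defection (T + 0)/2
  xu <- list(NULL, matrix(0.5, 4, 2))
  ru <- avg_reward_sa(g, xu, 1)
  expect_equal(unname(ru[, "c"]), rep((1 + g$S) / 2, 4))
  expect_equal(unname(ru[, "d"]), rep(g$T / 2, 4))
  # state-independence when the opponent's frequencies are state-independent
  expect_true(all(apply(ru, 2, function(col) diff(range(col)) == 0)))
  # seat symmetry: agent 2 against a defecting agent 1
  x2 <- list(action_frequencies(alld, 0), NULL)
  r2 <- avg_reward_sa(g, x2, 2)
  expect_equal(unname(r2[, "c"]), rep(g$S, 4))
})

test_that("averaged transitions are valid distributions with the right support", {
  g <- fig_game
  x <- list(action_frequencies(wsls, 0.2), action_frequencies(alld, 0))
  p1 <- avg_transition_agent(g, x, 1)
  for (s in 1:4) for (a in 1:2) expect_equal(sum(p1[s, a, ]), 1)
  # opponent pure d: cooperating leads surely to cd
  expect_equal(unname(p1[, "c", "cd"]), rep(1, 4))
  xu <- list(action_frequencies(wsls, 0.2), matrix(0.5, 4, 2))
  pu <- avg_transition_agent(g, xu, 1)
  expect_equal(unname(pu[, "c", "cc"]), rep(0.5, 4))
  expect_equal(unname(pu[, "c", "cd"]), rep(0.5, 4))
  # joint transition matrix rows sum to one; pure defectors drive all to dd
  xd <- list(action_frequencies(alld, 0), action_frequencies(alld, 0))
  pj <- avg_transition_joint(g, xd)
  expect_prob_rows(pj)
  expect_equal(unname(pj[, "dd"]), rep(1, 4))
  # eps = 0 WSLS pair cycles deterministically: cc->cc, cd->dd, dc->dd, dd->cc
  xw <- list(action_frequencies(wsls, 0), action_frequencies(wsls, 0))
  pw <- avg_transition_joint(g, xw)
  expect_equal(unname(diag(pw)[1]), 1)
  expect_equal(unname(pw["cd", "dd"]), 1)
  expect_equal(unname(pw["dc", "dd"]), 1)
  expect_equal(unname(pw["dd", "cc"]), 1)
})

test_that("state values solve the Bellman system in closed-form cases", {
  g <- fig_game
  xd <- list(action_frequencies(alld, 0), action_frequencies(alld, 0))
  v <- state_values(g, xd, 1, 0.5)
  expect_equal(v[["dd"]], 0)  # absorbing mutual defection earns 0 forever
  allc <- rep("c", 4)
  xc <- list(action_frequencies(allc, 0), action_frequencies(allc, 0))
  for (delta in c(0, 0.5, 0.9)) {
    vc <- state_values(g, xc, 1, delta)
    expect_equal(vc[["cc"]], 1 / (1 - delta))
  }
  # delta = 0 reduces to the strategy-average state reward
  xr <- list(action_frequencies(gt, 0.1), action_frequencies(wsls, 0.3))
  expect_equal(unname(state_values(g, xr, 2, 0)),
               avg_state_reward(g, xr, 2))
})

test_that("qualities and next-state values satisfy the Bellman identities", {
  g <- fig_game
  set.seed(7)
  for (rep in 1:5) {
    x <- list(action_frequencies(strategy_from_index(sample(0:15, 1)), runif(1, 0, 0.5)),
              action_frequencies(strategy_from_index(sample(0:15, 1)), runif(1, 0, 0.5)))
    delta <- runif(1, 0, 0.95)
    for (i in 1:2) {
      qbar <- avg_quality(g, x, i, delta)
      v <- state_values(g, x, i, delta)
      # consistency: own-strategy average of qualities is the state value
      expect_equal(unname(rowSums(x[[i]] * qbar)), unname(v), tolerance = 1e-10)
      # next-state expectation equals the transition-weighted state values
      nsv <- next_state_value(g, x, i, delta)
      p <- avg_transition_agent(g, x, i)
      direct <- qbar
      for (s in 1:4) for (a in 1:2) direct[s, a] <- sum(p[s, a, ] * v)
      expect_equal(nsv, direct, tolerance = 1e-10)
    }
    # delta = 0: qualities collapse to the average reward
    expect_equal(avg_quality(g, x, 1, 0), avg_reward_sa(g, x, 1))
  }
  # all-cooperate pair: q(cc, c) = 1 + delta/(1 - delta)
  allc <- rep("c", 4)
  xc <- list(action_frequencies(allc, 0), action_frequencies(allc, 0))
  qc <- avg_quality(g, xc, 1, 0.8)
  expect_equal(qc["cc", "c"], 1 + 0.8 / 0.2)
})

test_that("the deterministic map is fixed at strategy-consistent qualities", {
  g <- fig_game
  # alpha = 0 is the identity
  set.seed(1)
  q0 <- random_value_tables(g, 0.9, 2)
  p0 <- learner_params(0, 0.1, 0.9)
  expect_equal(det_update(q0, g, p0), lapply(q0, as_value_table))
  # alpha = 1 maps straight onto the strategy-average target
  p1 <- learner_params(1, 0.1, 0.9)
  x <- joint_frequencies(q0, 0.1)
  one <- det_update(q0, g, p1)
  for (i in 1:2) {
    target <- avg_reward_sa(g, x, i) + 0.9 * next_state_value(g, x, i, 0.9)
    expect_equal(one[[i]], target, tolerance = 1e-12)
  }
  # the strategy-average qualities of each named equilibrium (at parameters
  # where it is analytically stable) are fixed points with residual < 1e-10
  cases <- list(list(pure = alld, eps = 0.2, delta = 0.9),
                list(pure = wsls, eps = 0.01, delta = 0.98),
                list(pure = gt, eps = 0.01, delta = 0.6))
  for (cs in cases) {
    qbar <- pair_qualities(g, cs$pure, cs$eps, cs$delta)
    expect_identical(unname(greedy_strategy(qbar[[1]])), cs$pure)
    pr <- learner_params(0.5, cs$eps, cs$delta)
    nxt <- det_update(qbar, g, pr)
    resid <- max(abs(nxt[[1]] - qbar[[1]]), abs(nxt[[2]] - qbar[[2]]))
    expect_lt(resid, 1e-10)
  }
})

test_that("compiled and reference iterations agree trajectory-for-trajectory", {
  g <- fig_game
  p <- learner_params(0.2, 0.1, 0.9)
  set.seed(13)
  for (rep in 1:3) {
    q0 <- random_value_tables(g, 0.9, 2)
    a <- converge_and_classify(q0, g, p, max_iters = 50, window = 100,
                               use_cpp = TRUE)
    b <- converge_and_classify(q0, g, p, max_iters = 50, window = 100,
                               use_cpp = FALSE)
    expect_identical(a$label, b$label)
    expect_equal(a$q[[1]], b$q[[1]], tolerance = 1e-10)
    expect_equal(a$q[[2]], b$q[[2]], tolerance = 1e-10)
  }
})

test_that("convergence is immediate at a fixed point and deterministic overall", {
  g <- fig_game
  qa <- pair_qualities(g, alld, 0.2, 0.9)
  p <- learner_params(0.5, 0.2, 0.9)
  out <- converge_and_classify(qa, g, p)
  expect_identical(out$label, "AllD")
  expect_true(out$converged)
  expect_identical(out$iterations, 100L)  # exactly the confirmation window
  set.seed(5)
  q0 <- random_value_tables(g, 0.99, 2)
  r1 <- converge_and_classify(q0, g, learner_params(0.05, 0.05, 0.99))
  r2 <- converge_and_classify(q0, g, learner_params(0.05, 0.05, 0.99))
  expect_identical(r1, r2)
})

test_that("basin fractions are seeded, bounded and carry Wilson intervals", {
  bf <- basin_fractions(fig_game, 0.1, 0.1, 0.9, n_inits = 40, seed = 2)
  expect_equal(sum(bf$fraction), 1)
  expect_true(all(bf$lower <= bf$fraction & bf$fraction <= bf$upper))
  bf2 <- basin_fractions(fig_game, 0.1, 0.1, 0.9, n_inits = 40, seed = 2)
  expect_identical(bf, bf2)
})
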