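test_that("the local learning rate is 1/(t+1)", {
  expect_equal(local_rate(0), 1)
  expect_equal(local_rate(1), 0.5)
  expect_equal(local_rate(9), 0.1)
  expect_error(local_rate(-1))
})

test_that("the valuation table ends a batch as the running mean of its targets", {
  # eps = 0 makes the interaction deterministic, so the sampled targets can
  # be tracked by independent bookkeeping alongside the same trajectory
  g <- fig_game
  p <- learner_params(alpha = 0.3, epsilon = 0, delta = 0.5)
  q0 <- value_table_for_strategy(alld, 1, 0)
  agents <- list(batch_learner_state(q0, K = 6), batch_learner_state(q0, K = 6))
  out <- interaction_phase(agents, g, p, start_state = "dd")
  # independent bookkeeping: from dd the AllD pair revisits (dd, d) forever;
  # each target is delta * q_val(dd, d) at the time it is sampled
  targets <- numeric(0)
  qv <- 1
  for (k in 1:6) {
    targets <- c(targets, 0 + 0.5 * qv)
    qv <- mean(targets)
  }
  expect_equal(out$agents[[1]]$q_val["dd", "d"], mean(targets))
  expect_equal(out$agents[[1]]$counts["dd", "d"], 6)
  expect_identical(out$end_state, "dd")
  # hand-evaluated targets: 0.5 * 1, 0.5 * 0.5, 0.5 * mean(0.5, 0.25)
  expect_equal(targets[1:3], c(0.5, 0.25, 0.1875))
  # unvisited entries keep their batch-initial value and zero count
  expect_equal(out$agents[[1]]$q_val["cc", "c"], q0["cc", "c"])
  expect_equal(sum(out$agents[[1]]$counts), 6)
})

test_that("adaptation folds visited entries in at the global rate and resets", {
  q0 <- value_table(2)
  b <- batch_learner_state(q0, K = 4)
  b$q_val["cd", "d"] <- 5
  b$counts["cd", "d"] <- 3
  # alpha = 0 leaves acting values alone
  expect_equal(adaptation_phase(b, 0)$q_act, q0)
  # alpha = 1 copies the batch estimate on visited entries
  b1 <- adaptation_phase(b, 1)
  expect_equal(b1$q_act["cd", "d"], 5)
  expect_equal(b1$q_act["cc", "c"], 2)
  b2 <- adaptation_phase(b, 0.25)
  expect_equal(b2$q_act["cd", "d"], 0.75 * 2 + 0.25 * 5)
  expect_true(all(b2$counts == 0))
  expect_equal(b2$q_val, b2$q_act)
})

test_that("the compiled batch simulator matches the reference implementation", {
  # eps = 0 removes all randomness, so the two code paths must agree exactly
  g <- fig_game
  p <- learner_params(alpha = 0.3, epsilon = 0, delta = 0.9)
  q1 <- value_table_for_strategy(gt, 1, 0)
  q2 <- value_table_for_strategy(wsls, 1, 0)
  agents <- list(batch_learner_state(q1, K = 50), batch_learner_state(q2, K = 50))
  st <- "cc"
  for (b in 1:3) {
    out <- interaction_phase(agents, g, p, st)
    agents <- lapply(out$agents, adaptation_phase, alpha = p$alpha)
    st <- out$end_state
  }
  sm <- run_batch(g, p, K = 50, horizon = 150, n_samples = 1,
                  init = list(q1 = q1, q2 = q2, state = "cc"), seed = 1)
  expect_equal(unname(c(t(agents[[1]]$q_act))), unname(sm$final_q$q1[1, ]))
  expect_equal(unname(c(t(agents[[2]]$q_act))), unname(sm$final_q$q2[1, ]))
})

test_that("K = 1 reproduces the fully online trajectory on a shared stream", {
  p <- learner_params(0.1, 0.05, 0.9)
  so <- run_online(fig_game, p, horizon = 300, n_samples = 3,
                   record_every = 1, seed = 3)
  sb <- run_batch(fig_game, p, K = 1, horizon = 300, n_samples = 3,
                  record_every_batches = 1, seed = 3)
  expect_identical(so$codes, sb$codes)
  expect_equal(so$final_q$q1, sb$final_q$q1, tolerance = 1e-12)
  expect_equal(so$final_q$q2, sb$final_q$q2, tolerance = 1e-12)
})

test_that("batch runs are reproducible and absorbing without exploration", {
  p <- learner_params(0.3, 0.1, 0.9)
  a <- run_batch(fig_game, p, K = 64, horizon = 6400, n_samples = 5, seed = 9)
  b <- run_batch(fig_game, p, K = 64, horizon = 6400, n_samples = 5, seed = 9)
  expect_identical(a$series, b$series)
  init <- list(q1 = value_table_for_strategy(wsls, 1, 0),
               q2 = value_table_for_strategy(wsls, 1, 0), state = "cc")
  p0 <- learner_params(0.3, 0, 0.9)
  s <- run_batch(fig_game, p0, K = 64, horizon = 6400, n_samples = 2,
                 init = init, seed = 1)
  expect_true(all(s$series$frac_wsls == 1))
})

test_that("a robustness sweep reports final fractions and reach times", {
  sw <- robustness_sweep(fig_game, K_grid = c(32, 64), alpha_grid = 0.3,
                         epsilon_grid = 0.1, delta = 0.9, horizon = 6400,
                         n_samples = 4, threshold = 0, seed = 2)
  expect_identical(nrow(sw), 2L)
  # threshold 0 is reached at the first recorded time
  expect_equal(sw$reach_time_steps, c(0, 0))
  expect_true(all(sw$final_wsls_frac >= sw$wsls_lo & sw$final_wsls_frac <= sw$wsls_hi))
})
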