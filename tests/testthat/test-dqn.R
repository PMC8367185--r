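# DQN training-loop tests; MDP helpers live in helper-mdp.R

test_that("double-DQN targets use the evaluation argmax and target value", {
  em <- qnet_init(3, 4, seed = 1)
  tm <- qnet_init(3, 4, seed = 2)
  ns <- matrix(rnorm(15), 5, 3)
  batch <- list(reward = c(1, -7, 0.5, 2, -1),
                next_state = ns,
                terminal = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  got <- td_target(batch, em, tm, gamma = 0.9)
  # recomputed by hand from the networks' Q values
  qe <- q_values(em, ns); qt <- q_values(tm, ns)
  for (i in c(1, 3, 4)) {
    a_star <- which.max(qe[i, ])
    expect_equal(got[i], batch$reward[i] + 0.9 * qt[i, a_star])
  }
  expect_equal(got[c(2, 5)], c(-7, -1))      # terminal contract
  expect_equal(td_target(batch, em, tm, gamma = 0), batch$reward)
  # identical parameters reduce to the single-network target
  got_same <- td_target(batch, em, em, gamma = 0.9)
  expect_equal(got_same[1], batch$reward[1] + 0.9 * max(qe[1, ]))
})

test_that("regularized loss matches its closed form", {
  expect_equal(dqn_loss(1, 1, lambda = 0.7)$loss, 0)
  expect_equal(dqn_loss(5, 5, lambda = 0.5, r_reg = 4)$loss, 0.5)
  expect_equal(dqn_loss(1, 2, weights = 1, lambda = 0)$loss, 1)
  l <- dqn_loss(c(1, 3), c(2, 1), weights = c(1, 0.5), lambda = 0)
  expect_equal(l$loss, mean(c(1 * 1, 0.5 * 4)))
  expect_equal(l$td_error, c(1, -2))
  # non-negative; zero iff residuals zero and |Q| below the threshold
  set.seed(1)
  for (i in 1:20) {
    q <- rnorm(8, sd = 3)
    l <- dqn_loss(q, q + rnorm(8), lambda = 0.5, r_reg = 4)
    expect_gte(l$loss, 0)
  }
  expect_error(dqn_loss(NaN, 1), "non-finite")
})

test_that("prioritized sampling follows priority^alpha within multinomial bounds", {
  tr <- list(state = matrix(0, 2, 1), action = c(0L, 0L),
             reward = c(0, 0), next_state = matrix(0, 2, 1),
             terminal = c(TRUE, TRUE))
  buf <- replay_buffer(tr, alpha = 1, beta = 0.4)
  buf$priority <- c(3, 1)
  set.seed(11)
  draws <- replay_sample(buf, 1e4)$index
  p_hat <- mean(draws == 1L)
  # exact multinomial 99% bound at p = 0.75, n = 1e4
  expect_lt(abs(p_hat - 0.75), 2.576 * sqrt(0.75 * 0.25 / 1e4))
  # alpha = 0 flattens any priorities
  buf0 <- replay_buffer(tr, alpha = 0, beta = 0.4)
  buf0$priority <- c(100, 1)
  p0 <- mean(replay_sample(buf0, 1e4)$index == 1L)
  expect_lt(abs(p0 - 0.5), 2.576 * sqrt(0.25 / 1e4))
  # beta = 1 with uniform priorities gives unit importance weights
  bufu <- replay_buffer(tr, alpha = 0.6, beta = 1)
  expect_equal(replay_sample(bufu, 100)$weight, rep(1, 100))
  expect_error(replay_sample(buf, 3, replace = FALSE), "exceeds")
})

test_that("training is deterministic given the seed", {
  R <- matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE)
  NS <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  tr <- make_mdp_transitions(R, NS, n = 100, seed = 4)
  cf <- dqn_config(max_iter = 100, batch_size = 32, seed = 12)
  f1 <- train_dqn(tr, cf)
  f2 <- train_dqn(tr, cf)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the trained greedy policy solves a toy MDP like value iteration", {
  # two states, two actions: staying in state 1 pays 1, switching from
  # state 2 pays 2; optimal policy is (stay, switch)
  R <- matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE)
  NS <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  Qstar <- value_iteration(R, NS, gamma = 0.9)
  tr <- make_mdp_transitions(R, NS, n = 400, seed = 1)
  # faster target tracking and step size than the clinical defaults: the
  # tiny deterministic MDP needs the bootstrap to propagate magnitudes
  # (~10) quickly rather than cautiously
  fit <- train_dqn(tr, dqn_config(max_iter = 12000, lambda = 0, tau = 0.2,
                                  lr = 2e-3, batch_size = 64,
                                  patience = 1e9, seed = 3))
  qhat <- q_values(fit$model, tr$enc(1:2))
  expect_equal(max.col(qhat), max.col(Qstar))
  expect_lt(max(abs(qhat - Qstar)), 0.1)
})

test_that("a dominant action is ranked first on held-out states", {
  # terminal-only bandit: action 2 of 3 always pays +1, others -1
  set.seed(5)
  n <- 600
  X <- matrix(runif(n * 6), n, 6)
  a <- sample(0:2, n, replace = TRUE)
  tr <- list(state = X, action = as.integer(a),
             reward = ifelse(a == 1L, 1, -1),
             next_state = X * NA, terminal = rep(TRUE, n), arity = 3L)
  fit <- train_dqn(tr, dqn_config(max_iter = 1500, lambda = 0,
                                  batch_size = 64, seed = 7))
  held <- matrix(runif(300), 50, 6)
  q <- q_values(fit$model, held)
  expect_gte(mean(max.col(q) == 2L), 0.99)
})

test_that("divergent inputs abort with a diagnostic", {
  tr <- list(state = matrix(c(0, 1), 2, 1),
             action = c(0L, 5L),  # out of range for arity 2
             reward = c(0, 0), next_state = matrix(0, 2, 1),
             terminal = c(TRUE, TRUE))
  expect_error(train_dqn(tr, dqn_config(max_iter = 10, seed = 1),
                         arity = 2L), "range")
})
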