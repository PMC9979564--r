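rand_head_net <- function(seed = 1, input_dim = 4, n_actions = 5) {
  # zero heads make fresh nets output Q = 0; randomize them for target tests
  withr::with_seed(seed, {
    net <- dueling_net(input_dim, n_actions, hidden_sizes = c(8, 8))
    net$params$Wv[] <- rnorm(length(net$params$Wv), 0, 0.5)
    net$params$Wa[] <- rnorm(length(net$params$Wa), 0, 0.5)
    net$params$ba[] <- rnorm(n_actions, 0, 0.5)
    net$target <- net$params
    net
  })
}

test_that("dueling decomposition: zero net, value shift, centered advantages", {
  net <- dueling_net(3, 4, init = "zero")
  s <- matrix(rnorm(9), 3, 3)
  expect_equal(q_values(net, s), matrix(0, 3, 4))

  net2 <- rand_head_net(2, input_dim = 3, n_actions = 4)
  q0 <- q_values(net2, s)
  # advantages are mean-centered: the state value is the row mean of Q
  fwd <- sepsisrl:::net_forward(net2$params, s)
  expect_equal(rowSums(fwd$A), rep(0, 3), tolerance = 1e-12)
  expect_equal(rowMeans(q0), fwd$V)
  # constant added to the value head shifts all Q, leaving the argmax fixed
  net3 <- net2
  net3$params$bv <- net3$params$bv + 5
  q1 <- q_values(net3, s)
  expect_equal(q1, q0 + 5)
  expect_equal(max.col(q1), max.col(q0))

  expect_error(q_values(net2, matrix(0, 2, 7)), "dimension")
})

test_that("double-DQN target decouples selection from evaluation", {
  net <- rand_head_net(3)
  tgt <- rand_head_net(4) # a genuinely different network
  s2 <- matrix(rnorm(8 * 4), 8, 4)
  tr <- list(
    next_state = s2, reward = rnorm(8),
    terminal = c(TRUE, rep(FALSE, 7))
  )
  y <- double_dqn_target(net, tr, discount = 0.9, target_net = tgt)
  # terminal transition bootstraps nothing
  expect_equal(y[1], tr$reward[1])
  # brute force: argmax under the online net, value under the target net
  q_on <- q_values(net, s2)
  q_tg <- q_values(tgt, s2)
  manual <- tr$reward + 0.9 * q_tg[cbind(1:8, max.col(q_on, ties.method = "first"))]
  manual[1] <- tr$reward[1]
  expect_equal(y, manual)
  # with target = online copy it reduces to the plain Q-learning target
  y2 <- double_dqn_target(net, tr, discount = 0.9)
  manual2 <- tr$reward + 0.9 * apply(q_on, 1, max)
  manual2[1] <- tr$reward[1]
  expect_equal(y2, manual2)
})

test_that("one DDDQN step reports the pre-step mean squared residual", {
  net <- rand_head_net(5)
  batch <- list(
    state = matrix(rnorm(6 * 4), 6, 4),
    action = sample(1:5, 6, replace = TRUE),
    reward = rnorm(6),
    next_state = matrix(rnorm(6 * 4), 6, 4),
    terminal = rep(FALSE, 6)
  )
  y <- double_dqn_target(net, batch, 0.95)
  qsa <- q_estimate(net, batch$state, batch$action)
  res <- dddqn_update_step(net, batch, 0.95, learning_rate = 1e-3)
  expect_equal(res$loss, mean((qsa - y)^2))

  # an already-consistent batch: zero loss, parameters untouched
  net0 <- dueling_net(4, 5, init = "zero")
  batch0 <- list(
    state = batch$state, action = batch$action,
    reward = rep(0, 6), next_state = batch$next_state,
    terminal = rep(TRUE, 6)
  )
  r0 <- dddqn_update_step(net0, batch0, 0.95)
  expect_equal(r0$loss, 0)
  expect_identical(r0$net$params$Wa, net0$params$Wa)
  expect_identical(r0$net$params$W, net0$params$W)
})

test_that("repeated updates reach the fixed point on a deterministic chain", {
  # two states, two actions, deterministic swap dynamics and rewards
  withr::with_seed(6, {
    net <- dueling_net(2, 2, hidden_sizes = c(8, 8), target_sync_period = 50)
    s <- rbind(c(1, 0), c(0, 1))
    batch <- list(
      state = s[c(1, 1, 2, 2), ],
      action = c(1L, 2L, 1L, 2L),
      reward = c(1, 0.5, 0, -0.5),
      next_state = s[c(2, 1, 1, 2), ],
      terminal = rep(FALSE, 4)
    )
    # coarse phase followed by a fine phase (annealed step size)
    loss <- NA
    for (lr in c(1e-2, 5e-4)) {
      for (i in 1:3000) {
        r <- dddqn_update_step(net, batch, 0.9, learning_rate = lr)
        net <- r$net
        loss <- r$loss
      }
    }
    expect_lt(loss, 1e-3)
  })
})

test_that("weight updates are masked, capped, and inert at zero step size", {
  w <- reward_weights(rep(0.5, 6))
  demo <- list(state = matrix(rnorm(20), 10, 2), action = sample(1:4, 10, TRUE))
  net <- dueling_net(2, 4, init = "zero")
  psi <- matrix(rnorm(24), 4, 6)
  expect_identical(
    update_reward_weights(w, demo, net, 0, reward_spec("sepsis_all"), psi),
    w
  )
  w2 <- update_reward_weights(w, demo, net, 0.2, reward_spec("sepsis3.0"), psi)
  expect_equal(as.numeric(w2)[3:6], rep(0.5, 4)) # outside the index set: frozen
  expect_warning(
    w3 <- update_reward_weights(w, demo, net, 1e6, reward_spec("sepsis_all"),
      psi,
      weight_cap = 2
    ),
    "clipped"
  )
  expect_true(all(abs(as.numeric(w3)) <= 2))
})

test_that("training is reproducible and its trace matches the schedule", {
  co <- small_cohort(n = 40, horizon = 8)
  cfg <- dirl_config(
    reward_spec = reward_spec("sepsis3.0_4.0"),
    episodes = 3, transitions_per_episode = 80, seed = 5
  )
  f1 <- train_dirl(co, cfg)
  f2 <- train_dirl(co, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$weights, f2$weights)
  expect_equal(nrow(f1$trace), 3)
  expect_equal(length(f1$losses), 3 * 80)
  # empty schedule: untouched weights, empty trace
  cfg0 <- dirl_config(episodes = 0, transitions_per_episode = 0, seed = 5)
  f0 <- train_dirl(co, cfg0)
  expect_equal(nrow(f0$trace), 0)
  expect_identical(f0$weights, cfg0$initial_weights)
  # greedy actions are valid grid cells
  acts <- greedy_actions(f1, co[!is.na(co$action), ][1:20, ])
  expect_true(all(acts %in% 0:24))
})

test_that("training loss falls below its starting level on a toy cohort", {
  co <- small_cohort(n = 60, horizon = 10, seed = 13)
  cfg <- dirl_config(
    reward_spec = reward_spec("sepsis_all"),
    episodes = 8, transitions_per_episode = 300, seed = 8,
    learning_rate_q = 3e-3, learning_rate_w = 0, # fixed rewards: pure Q fit
    discount = 0.5 # short effective horizon keeps the Q scale stationary
  )
  fit <- train_dirl(co, cfg)
  expect_lt(fit$trace$loss[8], fit$trace$loss[1])
})

test_that("planted reward weights are recovered from demonstrations", {
  wstar <- reward_weights(c(0, 0, 0, 0, 2.5, -2.5))
  co <- suppressWarnings(simulate_cohort(cohort_config(
    n_patients = 3000, horizon = 12, seed = 101, hazard_intercept = -17,
    behavior_reward_weights = wstar, behavior_temperature = 0.6,
    behavior_epsilon = 0.15
  )))
  cfg <- dirl_config(
    reward_spec = reward_spec("sepsis_all"),
    episodes = 12, transitions_per_episode = 400, seed = 1,
    initial_weights = reward_weights(rep(0, 6)), demo_batch_size = 1e9
  )
  w <- as.numeric(train_dirl(co, cfg)$weights)
  expect_gt(w[5], 0) # oxygenation gains rewarded
  expect_lt(w[6], 0) # prothrombin prolongation penalized
  expect_true(all(rank(-abs(w))[5:6] <= 2)) # the planted pair dominates
})
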