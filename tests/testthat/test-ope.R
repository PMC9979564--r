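test_that("cumulative ratios multiply stepwise and respect support", {
  set.seed(21)
  mdp <- random_mdp(n_states = 4, n_actions = 3, horizon = 6)
  pi_b <- random_policy(4, 3)
  tr <- sample_trajectories(mdp, pi_b, 200, seed = 31)

  # on-policy: every ratio is 1
  cr <- cumulative_ratios(tr, pi_b)
  expect_equal(cr$rho, rep(1, nrow(cr)))
  expect_equal(cr$omega, rep(1, nrow(cr)))

  # product structure against a per-trajectory scan
  pi_e <- random_policy(4, 3)
  cr2 <- cumulative_ratios(tr, pi_e)
  chk <- cr2 |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(ok = max(abs(omega - cumprod(rho))) < 1e-12)
  expect_true(all(chk$ok))

  # a deterministic evaluation policy zeroes omega from the first disagreement
  pi_det <- deterministic_policy(c(1, 2, 1, 3), 3)
  cr3 <- cumulative_ratios(tr, pi_det)
  zero_chk <- cr3 |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(ok = {
      j <- which(rho == 0)[1]
      is.na(j) || all(omega[j:dplyr::n()] == 0)
    })
  expect_true(all(zero_chk$ok))

  # support violation is detected, not silently dropped
  tr_bad <- tr
  tr_bad$behavior_prob[3] <- 0
  expect_error(cumulative_ratios(tr_bad, pi_e), "support violation")
})

test_that("cumulative ratios are a martingale with unit mean", {
  set.seed(22)
  mdp <- random_mdp(n_states = 3, n_actions = 3, horizon = 5)
  pols <- list(e = random_policy(3, 3), b = soften_policy(random_policy(3, 3), 0.5))
  tr <- sample_trajectories(mdp, pols$b, 20000, seed = 7)
  cr <- cumulative_ratios(tr, pols$e)
  for (t in 0:(mdp$horizon - 1)) {
    om <- cr$omega[cr$t == t]
    se <- sd(om) / sqrt(length(om))
    expect_lt(abs(mean(om) - 1), 3 * se + 1e-9)
  }
})

test_that("IS reduces on-policy and is unbiased off-policy", {
  set.seed(23)
  mdp <- random_mdp(n_states = 5, n_actions = 3, horizon = 6, discount = 0.95)
  pi_b <- soften_policy(random_policy(5, 3), 0.4)
  pi_e <- random_policy(5, 3)
  tr <- sample_trajectories(mdp, pi_b, 400, seed = 8)

  # on-policy IS is the Monte-Carlo mean return
  mc <- tr |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(ret = sum(reward * mdp$discount^t))
  expect_equal(
    estimate_is(tr, pi_b, discount = mdp$discount)$estimate,
    mean(mc$ret)
  )

  # zero rewards estimate zero
  tr0 <- dplyr::mutate(tr, reward = 0)
  expect_equal(estimate_is(tr0, pi_e, discount = 0.9)$estimate, 0)

  # off-policy: replicate means bracket the exact value
  exact <- evaluate_policy_exact(mdp, pi_e)$value
  ests <- vapply(1:40, function(i) {
    tri <- sample_trajectories(mdp, pi_b, 300, seed = 100 + i)
    estimate_is(tri, pi_e, discount = mdp$discount)$estimate
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exact), 3 * se)
})

test_that("step-WIS self-normalizes and tracks the on-policy mean", {
  set.seed(24)
  mdp <- random_mdp(n_states = 4, n_actions = 2, horizon = 5, discount = 0.9)
  pi_b <- soften_policy(random_policy(4, 2), 0.5)
  pi_e <- random_policy(4, 2)

  # n = 1: reduces to that trajectory's plain return
  tr1 <- sample_trajectories(mdp, pi_b, 1, seed = 9)
  ret1 <- sum(tr1$reward * mdp$discount^tr1$t)
  expect_equal(
    estimate_step_wis(tr1, pi_e, discount = mdp$discount)$estimate, ret1
  )

  # large-n off-policy agreement with the exact value
  exact <- evaluate_policy_exact(mdp, pi_e)$value
  tr <- sample_trajectories(mdp, pi_b, 8000, seed = 10)
  wis <- estimate_step_wis(tr, pi_e, discount = mdp$discount)
  is_res <- estimate_is(tr, pi_e, discount = mdp$discount)
  se <- sd(is_res$per_trajectory) / sqrt(is_res$n)
  expect_lt(abs(wis$estimate - exact), 4 * se)
})

test_that("fitted value models recover tabular truth", {
  set.seed(25)
  mdp <- random_mdp(n_states = 4, n_actions = 2, horizon = 60, discount = 0.9)
  pi_b <- soften_policy(random_policy(4, 2), 0.6)
  pi_e <- random_policy(4, 2)
  tr <- sample_trajectories(mdp, pi_b, 300, seed = 11)

  model <- fit_value_model(tr, pi_e, 4, 2,
    discount = mdp$discount, sweeps = 200, quiet = TRUE
  )
  # noiseless rewards: empirical reward table is exact where visited
  seen <- unique(tr[, c("state", "action")])
  expect_equal(
    model$Rhat[cbind(seen$state, seen$action)],
    mdp$mean_reward[cbind(seen$state, seen$action)]
  )
  # long-horizon truncated truth vs fitted stationary Q
  q_true <- true_q_tables(mdp, pi_e)
  expect_lt(max(abs(model$Qhat - matrix(q_true[1, , ], 4))), 0.05)
  # V-hat consistency with the evaluation policy
  expect_equal(model$Vhat, rowSums(unclass(pi_e) * model$Qhat), tolerance = 1e-9)
})

test_that("DR telescopes with a perfect model and collapses to IS with none", {
  # deterministic MDP: transitions and initial state degenerate
  P <- array(0, c(3, 2, 3))
  P[1, 1, 2] <- 1; P[1, 2, 3] <- 1
  P[2, , 1] <- 1; P[3, , 1] <- 1
  mdp <- tabular_mdp(P, matrix(c(1, -1, 0.5, 0, 0.2, -0.3), 3, 2),
    c(1, 0, 0),
    discount = 0.95, horizon = 6
  )
  set.seed(26)
  pi_b <- random_policy(3, 2)
  tr <- sample_trajectories(mdp, pi_b, 50, seed = 12)
  exact <- evaluate_policy_exact(mdp, pi_b)$value
  res <- estimate_dr(tr, pi_b,
    model = perfect_value_model(mdp, pi_b),
    discount = mdp$discount
  )
  expect_equal(res$estimate, exact, tolerance = 1e-10)
  expect_lt(max(abs(res$per_trajectory - exact)), 1e-10)

  # zero model: DR == IS and WDR == step-WIS, per trajectory
  mdp2 <- random_mdp(n_states = 4, n_actions = 3, horizon = 7)
  pi_b2 <- soften_policy(random_policy(4, 3), 0.4)
  pi_e2 <- random_policy(4, 3)
  tr2 <- sample_trajectories(mdp2, pi_b2, 100, seed = 13)
  zm <- zero_value_model(4, 3)
  expect_lt(max(abs(
    estimate_dr(tr2, pi_e2, model = zm, discount = 0.9)$per_trajectory -
      estimate_is(tr2, pi_e2, discount = 0.9)$per_trajectory
  )), 1e-12)
  expect_lt(max(abs(
    estimate_wdr(tr2, pi_e2, model = zm, discount = 0.9)$per_trajectory -
      estimate_step_wis(tr2, pi_e2, discount = 0.9)$per_trajectory
  )), 1e-12)
  # NULL model behaves as the zero model
  expect_equal(
    estimate_dr(tr2, pi_e2, discount = 0.9)$estimate,
    estimate_is(tr2, pi_e2, discount = 0.9)$estimate
  )
})

test_that("WDR with one trajectory equals unit-weight DR", {
  set.seed(27)
  mdp <- random_mdp(n_states = 3, n_actions = 2, horizon = 5, discount = 0.9)
  pi_b <- soften_policy(random_policy(3, 2), 0.5)
  pi_e <- random_policy(3, 2)
  tr1 <- sample_trajectories(mdp, pi_b, 1, seed = 14)
  model <- fit_value_model(tr1, pi_e, 3, 2, discount = 0.9, quiet = TRUE)
  wdr <- estimate_wdr(tr1, pi_e, model = model, discount = 0.9)$estimate
  # unit-weight DR: additive form with all ratios 1
  m <- dplyr::arrange(tr1, t)
  qh <- model$Qhat[cbind(m$state, m$action)]
  vh <- model$Vhat[m$state]
  manual <- sum(0.9^m$t * (m$reward - qh + vh))
  expect_equal(wdr, manual, tolerance = 1e-12)
})

test_that("DW reduces to IS in its degenerate regimes", {
  set.seed(28)
  mdp <- random_mdp(n_states = 4, n_actions = 3, horizon = 1)
  pi_b <- soften_policy(random_policy(4, 3), 0.4)
  pi_e <- random_policy(4, 3)
  tr <- sample_trajectories(mdp, pi_b, 60, seed = 15)
  model <- fit_value_model(tr, pi_e, 4, 3, discount = 1, quiet = TRUE)
  # T = 1: the running mean equals the current estimate
  expect_lt(max(abs(
    estimate_dw(tr, pi_e, model = model, discount = 1)$per_trajectory -
      estimate_is(tr, pi_e, discount = 1)$per_trajectory
  )), 1e-12)

  # constant Q-hat at gamma = 1: the correction vanishes at every step
  mdp2 <- random_mdp(n_states = 3, n_actions = 2, horizon = 8, discount = 1)
  tr2 <- sample_trajectories(mdp2, soften_policy(random_policy(3, 2), 0.5),
    80,
    seed = 16
  )
  pe2 <- random_policy(3, 2)
  cm <- value_model(matrix(2.5, 3, 2), pe2)
  expect_lt(max(abs(
    estimate_dw(tr2, pe2, model = cm, discount = 1)$per_trajectory -
      estimate_is(tr2, pe2, discount = 1)$per_trajectory
  )), 1e-12)
})

test_that("DWDR matches its own expansion identity", {
  set.seed(29)
  mdp <- random_mdp(n_states = 4, n_actions = 3, horizon = 6, discount = 0.97)
  pi_b <- soften_policy(random_policy(4, 3), 0.4)
  pi_e <- random_policy(4, 3)
  tr <- sample_trajectories(mdp, pi_b, 50, seed = 17)
  model <- fit_value_model(tr, pi_e, 4, 3, discount = 0.97, quiet = TRUE)
  g <- 0.97
  dwdr <- estimate_dwdr(tr, pi_e, model = model, discount = g)
  is_r <- estimate_is(tr, pi_e, discount = g)
  dw_r <- estimate_dw(tr, pi_e, model = model, discount = g)
  cr <- cumulative_ratios(tr, pi_e)
  per_k <- dplyr::arrange(tr, subject_id, t) |>
    dplyr::mutate(omega = dplyr::arrange(cr, subject_id, t)$omega) |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(extra = sum(
      g^t * omega * model$Qhat[cbind(state, action)] +
        g^t * dplyr::lag(omega, default = 1) * model$Vhat[state]
    ))
  manual <- is_r$per_trajectory + dw_r$per_trajectory - per_k$extra
  expect_lt(max(abs(dwdr$per_trajectory - manual)), 1e-12)

  # zero rewards and zero model estimate zero
  tr0 <- dplyr::mutate(tr, reward = 0)
  expect_equal(
    estimate_dwdr(tr0, pi_e, model = zero_value_model(4, 3), discount = g)$estimate,
    0
  )
})

test_that("DW diagnostics follow their defining identities", {
  set.seed(30)
  mdp <- random_mdp(n_states = 3, n_actions = 2, horizon = 10, discount = 1)
  pi_b <- soften_policy(random_policy(3, 2), 0.5)
  tr <- sample_trajectories(mdp, pi_b, 1, seed = 18)
  model <- perfect_value_model(mdp, pi_b)
  dg <- dw_diagnostics(tr, model,
    true_q = true_q_tables(mdp, pi_b),
    discount = 1
  )
  # perfect model: all error series vanish
  expect_true(all(abs(dg$delta) < 1e-12))
  expect_true(all(abs(dg$delta2) < 1e-12))
  # gamma = 1: phi is exactly -1/t and decays toward zero
  tt <- dg$t[-1]
  expect_equal(dg$phi[-1], -1 / tt)
  expect_lt(abs(dg$phi[nrow(dg)]), 1 / (nrow(dg) - 1) + 1e-12)
  # backward return at gamma = 1 is the running reward sum
  r <- dplyr::arrange(tr, t)$reward
  expect_equal(dg$v_back, cumsum(r))
  # running mean at t = 0 equals the first estimate
  expect_equal(dg$q_hat_means[1], dg$q_hat[1])
})

test_that("DW bias bound is linear and honored on the benchmark", {
  expect_equal(dw_bias_bound(0, 3), 0)
  expect_equal(dw_bias_bound(24, 1.5), 2 * dw_bias_bound(12, 1.5))

  mdp <- benchmark_mdp(horizon = 10)
  pols <- benchmark_policies(mdp)
  bench <- run_estimator_benchmark(mdp, pols$eval, pols$behavior,
    n = 150, replicates = 30, seed = 19, estimators = c("IS", "DW")
  )
  r_max <- max(abs(mdp$mean_reward))
  expect_lt(
    abs(bench$bias[bench$estimator == "DW"]),
    dw_bias_bound(mdp$horizon, r_max)
  )
})

test_that("benchmark harness reports unbiased IS and flags degenerate runs", {
  mdp <- benchmark_mdp(horizon = 8)
  pols <- benchmark_policies(mdp)
  bench <- run_estimator_benchmark(mdp, pols$eval, pols$behavior,
    n = 200, replicates = 40, seed = 20
  )
  est <- attr(bench, "estimates")
  se_is <- sd(est[, "IS"]) / sqrt(nrow(est))
  expect_lt(abs(bench$bias[bench$estimator == "IS"]), 3 * se_is)
  expect_equal(bench$mse, bench$bias^2 + bench$variance * (39 / 40),
    tolerance = 1e-10
  )
  expect_warning(
    run_estimator_benchmark(mdp, pols$eval, pols$behavior,
      n = 20, replicates = 1, seed = 21, estimators = "IS"
    ),
    "variance"
  )
  # same seed gives bit-identical benchmarks
  b2 <- run_estimator_benchmark(mdp, pols$eval, pols$behavior,
    n = 200, replicates = 40, seed = 20
  )
  expect_identical(attr(bench, "estimates"), attr(b2, "estimates"))
})
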