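# Randomized small-MDP fixtures; all draws use the caller's RNG state so
# tests control seeding explicitly.

random_mdp <- function(n_states = 6, n_actions = 3, horizon = 8,
                       discount = 0.95, reward_noise_sd = 0,
                       reward_range = c(-1, 1)) {
  P <- array(stats::rgamma(n_states * n_actions * n_states, 1),
    c(n_states, n_actions, n_states)
  )
  P <- P / rep(apply(P, c(1, 2), sum), times = n_states)
  R <- matrix(
    stats::runif(n_states * n_actions, reward_range[1], reward_range[2]),
    n_states, n_actions
  )
  mu <- stats::rgamma(n_states, 1)
  tabular_mdp(P, R, mu / sum(mu), discount, horizon, reward_noise_sd)
}

random_policy <- function(n_states, n_actions, concentration = 1) {
  p <- matrix(stats::rgamma(n_states * n_actions, concentration), n_states, n_actions)
  policy_table(p / rowSums(p))
}

# soften a policy toward uniform: mixing keeps full support
soften_policy <- function(policy, eps = 0.3) {
  policy_table((1 - eps) * unclass(policy) + eps / ncol(policy))
}

# the fixed long-horizon benchmark used across estimator tests: moderate
# policy mismatch, gamma near 1, centered rewards
benchmark_mdp <- function(horizon = 20) {
  set.seed(20240901)
  random_mdp(
    n_states = 8, n_actions = 4, horizon = horizon, discount = 0.99,
    reward_range = c(-1, 1)
  )
}

benchmark_policies <- function(mdp, mismatch = 0.35) {
  set.seed(20240902)
  pi_e <- random_policy(mdp$n_states, mdp$n_actions, concentration = 2)
  pi_b <- policy_table(
    (1 - mismatch) * unclass(pi_e) +
      mismatch * matrix(1 / mdp$n_actions, mdp$n_states, mdp$n_actions)
  )
  list(eval = pi_e, behavior = pi_b)
}

small_cohort <- function(n = 60, horizon = 12, seed = 7, ...) {
  # fixed pre-calibrated hazard intercept keeps small fixtures fast
  suppressWarnings(simulate_cohort(cohort_config(
    n_patients = n, horizon = horizon, seed = seed,
    hazard_intercept = -17, ...
  )))
}
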