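#' Finite tabular MDP specification
#'
#' Constructs the ground-truth substrate used throughout the package to
#' validate off-policy estimators: a finite Markov decision process
#' \eqn{\langle S, A, P, R, \gamma \rangle} with an initial state
#' distribution \eqn{\mu} and a fixed evaluation horizon \eqn{T}.
#' Rewards may be stochastic: each realized reward is Gaussian around
#' `mean_reward[s, a]` with standard deviation `reward_noise_sd`.
#'
#' Time is indexed `t = 0, ..., T - 1` and the T-step discounted value is
#' \eqn{v^\pi_T = E[\sum_{t=0}^{T-1} \gamma^t r_t]}; this 0-based convention
#' is used consistently by every estimator in the package.
#'
#' @param transition numeric array of dimension `(S, A, S)`; `transition[s, a, ]`
#'   is the distribution of the next state and must sum to 1.
#' @param mean_reward numeric `(S, A)` matrix of mean rewards.
#' @param initial_dist probability vector of length `S` (\eqn{\mu}).
#' @param discount discount factor \eqn{\gamma \in [0, 1]}.
#' @param horizon positive integer number of decision steps \eqn{T}.
#' @param reward_noise_sd nonnegative reward noise standard deviation.
#'
#' @return An object of class `tabular_mdp`.
#' @examples
#' mdp <- tabular_mdp(
#'   transition = array(c(0.9, 0.1, 0.2, 0.8, 0.1, 0.9, 0.7, 0.3), c(2, 2, 2)),
#'   mean_reward = matrix(c(1, 0, 0, 1), 2, 2),
#'   initial_dist = c(1, 0), discount = 0.9, horizon = 5
#' )
#' evaluate_policy_exact(mdp, uniform_policy(mdp))$value
#' @export
tabular_mdp <- function(transition, mean_reward, initial_dist, discount,
                        horizon, reward_noise_sd = 0) {
  stopifnot(is.array(transition), length(dim(transition)) == 3)
  S <- dim(transition)[1]
  A <- dim(transition)[2]
  if (dim(transition)[3] != S) {
    stop("`transition` must have dimension (S, A, S)")
  }
  mean_reward <- as.matrix(mean_reward)
  if (!all(dim(mean_reward) == c(S, A))) {
    stop("`mean_reward` must be an (S, A) matrix matching `transition`")
  }
  if (length(initial_dist) != S) {
    stop("`initial_dist` must have length S")
  }
  row_sums <- apply(transition, c(1, 2), sum)
  if (any(abs(row_sums - 1) > 1e-9) || any(transition < 0)) {
    stop("every `transition[s, a, ]` row must be a probability vector (sum 1 within 1e-9)")
  }
  if (abs(sum(initial_dist) - 1) > 1e-9 || any(initial_dist < 0)) {
    stop("`initial_dist` must sum to 1 within 1e-9")
  }
  if (discount < 0 || discount > 1) stop("`discount` must lie in [0, 1]")
  horizon <- as.integer(horizon)
  if (horizon < 1) stop("`horizon` must be a positive count")
  if (reward_noise_sd < 0) stop("`reward_noise_sd` must be nonnegative")
  structure(
    list(
      n_states = S, n_actions = A, transition = transition,
      mean_reward = mean_reward, initial_dist = as.numeric(initial_dist),
      discount = discount, horizon = horizon,
      reward_noise_sd = reward_noise_sd
    ),
    class = "tabular_mdp"
  )
}

#' @export
print.tabular_mdp <- function(x, ...) {
  cat(sprintf(
    "<tabular_mdp> %d states, %d actions, horizon %d, discount %.3f, reward sd %.3f\n",
    x$n_states, x$n_actions, x$horizon, x$discount, x$reward_noise_sd
  ))
  invisible(x)
}

#' Stochastic policy table
#'
#' Validates an `(S, A)` matrix of action probabilities \eqn{\pi(a \mid s)}.
#' Deterministic policies are represented as one-hot rows so that every
#' estimator shares a single stochastic code path.
#'
#' @param probs numeric `(S, A)` matrix; each row must sum to 1.
#' @return The validated matrix, classed `policy_table`.
#' @export
policy_table <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("each policy row must be a probability vector (sum 1 within 1e-9)")
  }
  class(probs) <- c("policy_table", class(probs))
  probs
}

#' @rdname policy_table
#' @param mdp a [tabular_mdp()].
#' @export
uniform_policy <- function(mdp) {
  policy_table(matrix(1 / mdp$n_actions, mdp$n_states, mdp$n_actions))
}

#' @rdname policy_table
#' @param actions integer vector of length S giving the action taken in each state.
#' @param n_actions number of actions.
#' @export
deterministic_policy <- function(actions, n_actions) {
  p <- matrix(0, length(actions), n_actions)
  p[cbind(seq_along(actions), actions)] <- 1
  policy_table(p)
}

check_mdp_policy <- function(mdp, policy) {
  policy <- as.matrix(policy)
  if (nrow(policy) != mdp$n_states || ncol(policy) != mdp$n_actions) {
    stop(sprintf(
      "policy dimension (%d, %d) does not match MDP (%d states, %d actions)",
      nrow(policy), ncol(policy), mdp$n_states, mdp$n_actions
    ))
  }
  policy
}

#' Exact finite-horizon policy evaluation
#'
#' Computes the T-step discounted value of a policy by the backward Bellman
#' recursion \eqn{Q_t(s,a) = R(s,a) + \gamma E_{s'}[V_{t+1}(s')]},
#' \eqn{V_t(s) = E_{a \sim \pi}[Q_t(s,a)]}, with \eqn{V_T \equiv 0}. This is
#' the deterministic ground-truth oracle the off-policy estimators are
#' benchmarked against.
#'
#' @param mdp a [tabular_mdp()].
#' @param policy an `(S, A)` policy matrix.
#' @return A list with `value` (scalar \eqn{v^\pi_T} under \eqn{\mu}),
#'   `V` (a `(T + 1, S)` matrix, last row zero), and `Q` (a `(T, S, A)` array).
#' @export
evaluate_policy_exact <- function(mdp, policy) {
  policy <- check_mdp_policy(mdp, policy)
  S <- mdp$n_states; A <- mdp$n_actions; T_ <- mdp$horizon
  # flatten transition to an (S*A, S) matrix for fast expectation products
  P <- matrix(aperm(mdp$transition, c(3, 1, 2)), nrow = S, ncol = S * A)
  V <- matrix(0, T_ + 1, S)
  Q <- array(0, c(T_, S, A))
  for (t in T_:1) {
    ev <- matrix(crossprod(P, V[t + 1, ]), S, A) # E_{s'}[V_{t+1}(s')] per (s, a)
    Qt <- mdp$mean_reward + mdp$discount * ev
    Q[t, , ] <- Qt
    V[t, ] <- rowSums(policy * Qt)
  }
  list(value = sum(mdp$initial_dist * V[1, ]), V = V, Q = Q)
}

#' Per-step exact action-value tables
#'
#' Returns the exact \eqn{Q_t(s, a)} tables for `t = 0, ..., T - 1`, used as
#' the "perfect model" in doubly-robust and dueling-weight estimator tests.
#'
#' @inheritParams evaluate_policy_exact
#' @return A `(T, S, A)` array; entry `[t, s, a]` is \eqn{Q_{t-1}(s, a)}.
#' @export
true_q_tables <- function(mdp, policy) {
  evaluate_policy_exact(mdp, policy)$Q
}

# Sample n trajectories into flat matrices (rows = trajectories, cols = steps).
# Uses the current RNG state; callers own seeding.
sample_traj_mats <- function(mdp, policy, n) {
  S <- mdp$n_states; A <- mdp$n_actions; T_ <- mdp$horizon
  pol_cum <- t(apply(matrix(policy, S, A), 1, cumsum))
  # cumulative next-state distribution per flat (s, a) row
  trans_cum <- matrix(NA_real_, S * A, S)
  for (a in seq_len(A)) {
    trans_cum[(a - 1L) * S + seq_len(S), ] <-
      t(apply(matrix(mdp$transition[, a, ], S, S), 1, cumsum))
  }
  st <- matrix(NA_integer_, n, T_)
  ac <- matrix(NA_integer_, n, T_)
  rw <- matrix(NA_real_, n, T_)
  bp <- matrix(NA_real_, n, T_)
  nxt <- matrix(NA_integer_, n, T_)
  s <- sample.int(S, n, replace = TRUE, prob = mdp$initial_dist)
  for (t in seq_len(T_)) {
    u <- stats::runif(n)
    a <- rowSums(pol_cum[s, , drop = FALSE] < u) + 1L
    a[a > A] <- A
    u2 <- stats::runif(n)
    s2 <- rowSums(trans_cum[(a - 1L) * S + s, , drop = FALSE] < u2) + 1L
    s2[s2 > S] <- S
    r <- mdp$mean_reward[cbind(s, a)]
    if (mdp$reward_noise_sd > 0) r <- r + stats::rnorm(n, 0, mdp$reward_noise_sd)
    st[, t] <- s; ac[, t] <- a; rw[, t] <- r; nxt[, t] <- s2
    bp[, t] <- matrix(policy, S, A)[cbind(s, a)]
    s <- s2
  }
  list(
    state = st, action = ac, reward = rw, next_state = nxt,
    behavior_prob = bp, len = rep(T_, n), died = rep(FALSE, n),
    final_state = s
  )
}

#' Sample trajectories from a tabular MDP
#'
#' Draws `n` independent T-step trajectories under a stochastic behavior
#' policy, recording the behavior probability \eqn{\pi_b(a_t \mid s_t)} on
#' every step. Output is one tidy row per step.
#'
#' @inheritParams evaluate_policy_exact
#' @param n number of trajectories.
#' @param seed integer seed; the draw is bit-reproducible given `seed`.
#' @return A tibble with columns `subject_id`, `t` (0-based), `state`,
#'   `action`, `reward`, `next_state`, `behavior_prob`, `died`.
#' @export
sample_trajectories <- function(mdp, policy, n, seed) {
  policy <- check_mdp_policy(mdp, policy)
  if (length(seed) != 1 || is.na(suppressWarnings(as.integer(seed)))) {
    stop("`seed` must be a single integer")
  }
  stopifnot(n >= 1)
  m <- with_seed(as.integer(seed), sample_traj_mats(mdp, policy, n))
  traj_mats_to_tibble(m)
}

# Restore-on-exit seeded evaluation (keeps the caller's RNG stream intact).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

traj_mats_to_tibble <- function(m) {
  n <- nrow(m$state)
  T_ <- ncol(m$state)
  keep <- !is.na(m$state)
  tibble::tibble(
    subject_id = rep(seq_len(n), times = T_)[as.vector(keep)],
    t = rep(seq_len(T_) - 1L, each = n)[as.vector(keep)],
    state = m$state[keep],
    action = m$action[keep],
    reward = m$reward[keep],
    next_state = m$next_state[keep],
    behavior_prob = m$behavior_prob[keep],
    died = rep(m$died, times = T_)[as.vector(keep)]
  ) |>
    dplyr::arrange(.data$subject_id, .data$t)
}

# Inverse of traj_mats_to_tibble; pads ragged trajectories with NA.
as_traj_mats <- function(trajectories) {
  need <- c("subject_id", "t", "state", "action", "reward", "behavior_prob")
  miss <- setdiff(need, names(trajectories))
  if (length(miss)) stop("trajectory table lacks columns: ", paste(miss, collapse = ", "))
  ids <- unique(trajectories$subject_id)
  idx <- match(trajectories$subject_id, ids)
  tt <- trajectories$t + 1L
  n <- length(ids)
  T_ <- max(tt)
  mk <- function(col, mode = NA_real_) {
    m <- matrix(mode, n, T_)
    m[cbind(idx, tt)] <- trajectories[[col]]
    m
  }
  died <- rep(FALSE, n)
  if ("died" %in% names(trajectories)) {
    died <- as.logical(tapply(trajectories$died, idx, any))
  }
  list(
    state = mk("state", NA_integer_), action = mk("action", NA_integer_),
    reward = mk("reward"),
    next_state = if ("next_state" %in% names(trajectories)) mk("next_state", NA_integer_) else NULL,
    behavior_prob = mk("behavior_prob"),
    len = as.integer(tapply(tt, idx, max)),
    died = died, ids = ids
  )
}

#' Fast Monte-Carlo estimate of a policy's T-step value
#'
#' On-policy mean of \eqn{\sum_t \gamma^t r_t} over `n` sampled trajectories,
#' without materializing a step table. Used as the stochastic oracle that
#' exact dynamic programming is validated against.
#'
#' @inheritParams sample_trajectories
#' @return A list with `mean`, `se` (standard error), and `n`.
#' @export
mc_policy_value <- function(mdp, policy, n, seed) {
  policy <- check_mdp_policy(mdp, policy)
  with_seed(as.integer(seed), {
    S <- mdp$n_states; A <- mdp$n_actions; T_ <- mdp$horizon
    pol_cum <- t(apply(matrix(policy, S, A), 1, cumsum))
    trans_cum <- matrix(NA_real_, S * A, S)
    for (a in seq_len(A)) {
      trans_cum[(a - 1L) * S + seq_len(S), ] <-
        t(apply(matrix(mdp$transition[, a, ], S, S), 1, cumsum))
    }
    ret <- numeric(n)
    s <- sample.int(S, n, replace = TRUE, prob = mdp$initial_dist)
    g <- 1
    for (t in seq_len(T_)) {
      u <- stats::runif(n)
      a <- rowSums(pol_cum[s, , drop = FALSE] < u) + 1L
      a[a > A] <- A
      r <- mdp$mean_reward[cbind(s, a)]
      if (mdp$reward_noise_sd > 0) r <- r + stats::rnorm(n, 0, mdp$reward_noise_sd)
      ret <- ret + g * r
      u2 <- stats::runif(n)
      s <- rowSums(trans_cum[(a - 1L) * S + s, , drop = FALSE] < u2) + 1L
      s[s > S] <- S
      g <- g * mdp$discount
    }
    list(mean = mean(ret), se = stats::sd(ret) / sqrt(n), n = n)
  })
}

#' Read and write trajectory step tables
#'
#' Trajectories are serialized one record per step with columns
#' `subject_id, t, state, action, reward, next_state, behavior_prob, died`
#' (comma-separated, header row, `t` 0-based). The same format is used for
#' tabular-MDP trajectories (integer `state`) and, with a features sidecar,
#' for synthetic cohorts.
#'
#' @param trajectories a trajectory step tibble.
#' @param path file path.
#' @return `read_trajectories()` returns the step tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
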