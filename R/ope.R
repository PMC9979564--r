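#' Off-policy evaluation estimators
#'
#' @description
#' The estimator suite values an evaluation policy \eqn{\pi_e} from
#' trajectories logged under a behavior policy \eqn{\pi_b}, using the
#' cumulative importance ratio
#' \eqn{\omega_{0:t} = \prod_{i=0}^{t} \pi_e(a_i|s_i)/\pi_b(a_i|s_i)}
#' (with \eqn{\omega_{0:-1} = 1}):
#'
#' * **IS**: \eqn{\frac{1}{n}\sum_k \sum_t \omega_{0:t}\gamma^t r_t} — unbiased,
#'   high variance.
#' * **step-WIS**: self-normalized IS with per-horizon weights
#'   \eqn{\omega_{0:t}/\bar\omega_t}, \eqn{\bar\omega_t = \frac{1}{n}\sum_k \omega^{(k)}_{0:t}}.
#' * **DR**: doubly robust — the backward recursion
#'   \eqn{V^{(t)} = \hat V(s_t) + \rho_t (r_t + \gamma V^{(t+1)} - \hat Q(s_t,a_t))}
#'   with per-step ratio \eqn{\rho_t} (default), or the literal cumulative-ratio
#'   variant via `ratio_mode = "cumulative"`.
#' * **WDR**: DR with self-normalized horizon weights.
#' * **DW** (dueling weight): corrects each step's reward by the gap between the
#'   current value estimate and the running discount-weighted mean of past
#'   estimates,
#'   \eqn{\hat Q_{means}(s_t,a_t) = \frac{1}{t+1}\sum_{i=0}^t \gamma^i \hat Q(s_i,a_i)}:
#'   \eqn{\sum_t \omega_{0:t}\gamma^t (r_t + \hat Q(s_t,a_t) - \hat Q_{means}(s_t,a_t))},
#'   averaged over trajectories. No backward recursion is required.
#' * **DWDR**: the blend
#'   \eqn{\sum_t \omega_{0:t}\gamma^t (2 r_t - \hat Q_{means}(s_t,a_t)) - \omega_{0:t-1}\gamma^t \hat V(s_t)},
#'   trading a small variance increase for reduced bias.
#'
#' All estimators share one stochastic code path: deterministic evaluation
#' policies are passed as one-hot policy matrices. Trajectories may be ragged
#' (absorbing termination): steps past a trajectory's end contribute zero
#' reward and unit per-step ratio.
#'
#' @param trajectories a trajectory step tibble (integer `state`, `action`,
#'   `reward`, `behavior_prob` columns; see [sample_trajectories()]).
#' @param eval_policy `(S, A)` evaluation-policy matrix.
#' @param behavior_policy optional `(S, A)` behavior-policy matrix; when
#'   `NULL` the stored `behavior_prob` column is used.
#' @param model a [value_model()], or `NULL` for the zero model (reduces DR
#'   to IS and WDR to step-WIS).
#' @param discount discount factor \eqn{\gamma}.
#' @param ratio_mode `"step"` (default) or `"cumulative"` for the DR/WDR
#'   recursion ratio.
#' @return An `ope_result`: list with `estimator`, `estimate`,
#'   `per_trajectory`, `n`, and optionally `ci`.
#' @name ope_estimators
NULL

# ---- internal matrix cores ------------------------------------------------

# rho / omega matrices from trajectory matrices; carries omega forward past
# trajectory end (absorbing continuation with unit ratio).
ratio_mats <- function(m, eval_policy, behavior_policy = NULL) {
  n <- nrow(m$state); T_ <- ncol(m$state)
  obs <- !is.na(m$state)
  pe <- matrix(NA_real_, n, T_)
  pe[obs] <- eval_policy[cbind(m$state[obs], m$action[obs])]
  if (is.null(behavior_policy)) {
    pb <- m$behavior_prob
  } else {
    pb <- matrix(NA_real_, n, T_)
    pb[obs] <- behavior_policy[cbind(m$state[obs], m$action[obs])]
  }
  bad <- obs & (is.na(pb) | pb <= 0) & pe > 0
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "support violation: behavior probability is 0 but evaluation probability > 0 at trajectory %d, step t = %d",
      w[1], w[2] - 1L
    ))
  }
  rho <- pe / pb
  rho[obs & pe == 0 & pb == 0] <- 0
  rho[!obs] <- 1 # absorbing continuation
  omega <- rho
  if (T_ > 1) {
    for (t in 2:T_) omega[, t] <- omega[, t - 1] * rho[, t]
  }
  list(rho = rho, omega = omega, obs = obs)
}

disc_row <- function(gamma, T_) gamma^(seq_len(T_) - 1)

# Q-hat at realized (t, s, a); supports stationary (S x A) and per-step
# (T x S x A) models. Zero past trajectory end.
model_q_step <- function(m, model) {
  n <- nrow(m$state); T_ <- ncol(m$state)
  q <- matrix(0, n, T_)
  if (is.null(model)) return(q)
  obs <- !is.na(m$state)
  if (length(dim(model$Qhat)) == 3) {
    tt <- col(m$state)
    q[obs] <- model$Qhat[cbind(tt[obs], m$state[obs], m$action[obs])]
  } else {
    q[obs] <- model$Qhat[cbind(m$state[obs], m$action[obs])]
  }
  q
}

model_v_step <- function(m, model) {
  n <- nrow(m$state); T_ <- ncol(m$state)
  v <- matrix(0, n, T_)
  if (is.null(model)) return(v)
  obs <- !is.na(m$state)
  if (is.matrix(model$Vhat)) {
    tt <- col(m$state)
    v[obs] <- model$Vhat[cbind(tt[obs], m$state[obs])]
  } else {
    v[obs] <- model$Vhat[m$state[obs]]
  }
  v
}

zero_pad <- function(x) {
  x[is.na(x)] <- 0
  x
}

core_is <- function(m, rat, gamma) {
  T_ <- ncol(m$state)
  d <- disc_row(gamma, T_)
  rw <- zero_pad(m$reward)
  as.numeric((rat$omega * rw) %*% d)
}

core_wis <- function(m, rat, gamma) {
  T_ <- ncol(m$state)
  d <- disc_row(gamma, T_)
  rw <- zero_pad(m$reward)
  wbar <- colMeans(rat$omega)
  if (any(wbar == 0)) {
    warning("average cumulative ratio is 0 at some horizon; contribution set to 0")
  }
  wnorm <- sweep(rat$omega, 2, ifelse(wbar == 0, Inf, wbar), "/")
  as.numeric((wnorm * rw) %*% d)
}

core_dr <- function(m, rat, model, gamma, ratio_mode = "step") {
  n <- nrow(m$state); T_ <- ncol(m$state)
  ratio <- if (ratio_mode == "cumulative") rat$omega else rat$rho
  qh <- model_q_step(m, model)
  vh <- model_v_step(m, model)
  rw <- zero_pad(m$reward)
  vdr <- numeric(n)
  for (t in T_:1) {
    act <- m$len >= t
    vdr[act] <- vh[act, t] +
      ratio[act, t] * (rw[act, t] + gamma * vdr[act] - qh[act, t])
  }
  vdr
}

core_wdr <- function(m, rat, model, gamma) {
  n <- nrow(m$state); T_ <- ncol(m$state)
  d <- disc_row(gamma, T_)
  qh <- model_q_step(m, model)
  vh <- model_v_step(m, model)
  rw <- zero_pad(m$reward)
  wsum <- colSums(rat$omega)
  wnorm <- sweep(rat$omega, 2, ifelse(wsum == 0, Inf, wsum), "/")
  wprev <- cbind(rep(1 / n, n), wnorm[, -T_, drop = FALSE])
  contrib <- wnorm * (rw - qh) + wprev * vh
  # scale per-trajectory shares so their plain mean equals the aggregate
  n * as.numeric(contrib %*% d)
}

core_dw <- function(m, rat, model, gamma) {
  T_ <- ncol(m$state)
  d <- disc_row(gamma, T_)
  qh <- model_q_step(m, model)
  qh[!rat$obs] <- 0
  # running discount-weighted mean (1/(t+1)) * sum_{i<=t} gamma^i Q-hat_i
  qcum <- t(apply(sweep(qh, 2, d, "*"), 1, cumsum))
  if (T_ == 1) qcum <- matrix(qcum, ncol = 1)
  qmeans <- sweep(qcum, 2, seq_len(T_), "/")
  rw <- zero_pad(m$reward)
  summand <- (rw + qh - qmeans) * rat$omega
  summand[!rat$obs] <- 0
  as.numeric(sweep(summand, 2, d, "*") %*% rep(1, T_))
}

core_dwdr <- function(m, rat, model, gamma) {
  n <- nrow(m$state); T_ <- ncol(m$state)
  d <- disc_row(gamma, T_)
  qh <- model_q_step(m, model)
  qh[!rat$obs] <- 0
  qcum <- t(apply(sweep(qh, 2, d, "*"), 1, cumsum))
  if (T_ == 1) qcum <- matrix(qcum, ncol = 1)
  qmeans <- sweep(qcum, 2, seq_len(T_), "/")
  vh <- model_v_step(m, model)
  rw <- zero_pad(m$reward)
  om_prev <- cbind(rep(1, n), rat$omega[, -T_, drop = FALSE])
  summand <- rat$omega * (2 * rw - qmeans) - om_prev * vh
  summand[!rat$obs] <- 0
  as.numeric(sweep(summand, 2, d, "*") %*% rep(1, T_))
}

ope_result <- function(estimator, per_trajectory, aggregate = mean(per_trajectory)) {
  structure(
    list(
      estimator = estimator, estimate = aggregate,
      per_trajectory = per_trajectory, n = length(per_trajectory)
    ),
    class = "ope_result"
  )
}

#' @export
print.ope_result <- function(x, ...) {
  cat(sprintf("<ope_result> %s: %.6g (n = %d)\n", x$estimator, x$estimate, x$n))
  invisible(x)
}

#' @export
tidy.ope_result <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator, estimate = x$estimate, n = x$n,
    se = stats::sd(x$per_trajectory) / sqrt(x$n)
  )
}

# ---- public estimators ----------------------------------------------------

#' Cumulative importance ratios of logged trajectories
#'
#' Per-step ratios \eqn{\rho_t = \pi_e(a_t|s_t)/\pi_b(a_t|s_t)} and their
#' running products \eqn{\omega_{0:t}}. A zero behavior probability paired
#' with a nonzero evaluation probability is a support violation and raises
#' an error naming the offending step.
#'
#' @inheritParams ope_estimators
#' @return Tibble with `subject_id`, `t`, `rho`, `omega`.
#' @export
cumulative_ratios <- function(trajectories, eval_policy, behavior_policy = NULL) {
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  keep <- rat$obs
  tibble::tibble(
    subject_id = m$ids[row(keep)[keep]],
    t = col(keep)[keep] - 1L,
    rho = rat$rho[keep],
    omega = rat$omega[keep]
  ) |> dplyr::arrange(.data$subject_id, .data$t)
}

#' @rdname ope_estimators
#' @export
estimate_is <- function(trajectories, eval_policy, behavior_policy = NULL,
                        discount = 1) {
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  ope_result("IS", core_is(m, rat, discount))
}

#' @rdname ope_estimators
#' @export
estimate_step_wis <- function(trajectories, eval_policy, behavior_policy = NULL,
                              discount = 1) {
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  ope_result("step-WIS", core_wis(m, rat, discount))
}

#' @rdname ope_estimators
#' @export
estimate_dr <- function(trajectories, eval_policy, behavior_policy = NULL,
                        model = NULL, discount = 1,
                        ratio_mode = c("step", "cumulative")) {
  ratio_mode <- match.arg(ratio_mode)
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  ope_result("DR", core_dr(m, rat, model, discount, ratio_mode))
}

#' @rdname ope_estimators
#' @export
estimate_wdr <- function(trajectories, eval_policy, behavior_policy = NULL,
                         model = NULL, discount = 1) {
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  ope_result("WDR", core_wdr(m, rat, model, discount))
}

#' @rdname ope_estimators
#' @export
estimate_dw <- function(trajectories, eval_policy, behavior_policy = NULL,
                        model = NULL, discount = 1) {
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  ope_result("DW", core_dw(m, rat, model, discount))
}

#' @rdname ope_estimators
#' @export
estimate_dwdr <- function(trajectories, eval_policy, behavior_policy = NULL,
                          model = NULL, discount = 1) {
  m <- as_traj_mats(trajectories)
  rat <- ratio_mats(m, eval_policy, behavior_policy)
  ope_result("DWDR", core_dwdr(m, rat, model, discount))
}

# ---- value models ---------------------------------------------------------

#' Estimated value model for model-assisted estimators
#'
#' Bundles the reward estimate \eqn{\hat R}, action-value estimate
#' \eqn{\hat Q} and the induced state value
#' \eqn{\hat V(s) = E_{a \sim \pi_e}[\hat Q(s, a)]}. `Qhat` may be a
#' stationary `(S, A)` matrix or a per-step `(T, S, A)` array (e.g. the exact
#' tables from [true_q_tables()], the "perfect model").
#'
#' @param Qhat `(S, A)` matrix or `(T, S, A)` array.
#' @param eval_policy `(S, A)` evaluation-policy matrix used to derive `Vhat`.
#' @param Rhat optional `(S, A)` reward estimate.
#' @return A `value_model` with fields `Rhat`, `Qhat`, `Vhat`.
#' @export
value_model <- function(Qhat, eval_policy, Rhat = NULL) {
  if (length(dim(Qhat)) == 3) {
    T_ <- dim(Qhat)[1]; S <- dim(Qhat)[2]
    Vhat <- matrix(0, T_, S)
    for (t in seq_len(T_)) {
      Vhat[t, ] <- rowSums(eval_policy * matrix(Qhat[t, , ], S))
    }
  } else {
    Vhat <- rowSums(eval_policy * Qhat)
  }
  structure(list(Rhat = Rhat, Qhat = Qhat, Vhat = Vhat), class = "value_model")
}

#' @rdname value_model
#' @param mdp,policy an exact MDP and evaluation policy: builds the perfect
#'   per-step model from the true Bellman tables.
#' @export
perfect_value_model <- function(mdp, policy) {
  value_model(true_q_tables(mdp, policy), check_mdp_policy(mdp, policy),
    Rhat = mdp$mean_reward
  )
}

#' Fit a value model from logged trajectories
#'
#' \eqn{\hat R(s, a)} is the empirical mean reward per state-action pair and
#' \eqn{\hat Q} is obtained by `sweeps` rounds of fitted value iteration under
#' the evaluation policy on the empirically estimated transition model
#' (`method = "dp"`), or \eqn{\hat Q = \hat R} (`method = "reward"`). Unseen
#' state-action pairs fall back to the global mean reward and a uniform
#' transition row (with a warning).
#'
#' @inheritParams ope_estimators
#' @param n_states,n_actions dimensions of the state/action space.
#' @param method `"dp"` (fitted value iteration) or `"reward"`.
#' @param sweeps number of value-iteration sweeps.
#' @param quiet suppress the unseen-pair warning.
#' @return A [value_model()].
#' @export
fit_value_model <- function(trajectories, eval_policy, n_states, n_actions,
                            discount = 1, method = c("dp", "reward"),
                            sweeps = 50, quiet = FALSE) {
  method <- match.arg(method)
  s <- trajectories$state
  a <- trajectories$action
  r <- trajectories$reward
  s2 <- trajectories$next_state
  flat <- (a - 1L) * n_states + s
  cnt <- tabulate(flat, n_states * n_actions)
  rsum <- numeric(n_states * n_actions)
  rs <- tapply(r, flat, sum)
  rsum[as.integer(names(rs))] <- rs
  Rhat <- matrix(ifelse(cnt > 0, rsum / pmax(cnt, 1), mean(r)), n_states, n_actions)
  if (any(cnt == 0) && !quiet) {
    warning(sprintf(
      "%d state-action pairs unseen; falling back to the global mean reward",
      sum(cnt == 0)
    ))
  }
  if (method == "reward") {
    return(value_model(Rhat, eval_policy, Rhat = Rhat))
  }
  # empirical transition counts
  Pcnt <- matrix(0, n_states * n_actions, n_states)
  trip <- tapply(rep(1, length(flat)), list(flat, s2), sum)
  rows <- as.integer(rownames(trip))
  cols <- as.integer(colnames(trip))
  Pcnt[rows, cols] <- ifelse(is.na(trip), 0, trip)
  tot <- rowSums(Pcnt)
  Phat <- Pcnt / pmax(tot, 1)
  Phat[tot == 0, ] <- 1 / n_states
  Q <- matrix(0, n_states, n_actions)
  for (k in seq_len(sweeps)) {
    V <- rowSums(eval_policy * Q)
    Q <- Rhat + discount * matrix(Phat %*% V, n_states, n_actions)
  }
  value_model(Q, eval_policy, Rhat = Rhat)
}

#' @rdname value_model
#' @param n_states,n_actions dimensions for an all-zero model (reduces DR to
#'   IS and WDR to step-WIS).
#' @export
zero_value_model <- function(n_states, n_actions) {
  value_model(matrix(0, n_states, n_actions),
    matrix(1 / n_actions, n_states, n_actions),
    Rhat = matrix(0, n_states, n_actions)
  )
}

# ---- diagnostics ----------------------------------------------------------

#' Dueling-weight estimator diagnostics
#'
#' Per-step diagnostic series for one trajectory: the running
#' discount-weighted mean \eqn{\hat Q_{means}}, the model error
#' \eqn{\Delta = \hat Q - Q} (exact when `true_q` is supplied), the
#' centered series \eqn{\Delta_1 = Q - Q_{means}},
#' \eqn{\Delta_2 = \Delta - \Delta_{means}}, the discount imbalance
#' \eqn{\phi^{t+2} = \gamma^t - (\gamma^t + \cdots + \gamma^0)/t} (defined
#' for \eqn{t \ge 1}; at \eqn{\gamma = 1} it equals \eqn{-1/t} and vanishes
#' with t), the backward discounted return
#' \eqn{V_t^{back} = r_t + \gamma r_{t-1} + \cdots + \gamma^t r_0}, and the
#' behavior-model mismatch \eqn{\delta = 1 - \pi_b/\hat\pi_b} (0 when the
#' behavior policy is known).
#'
#' @param traj a single trajectory (step tibble for one subject).
#' @param model a [value_model()].
#' @param true_q optional exact `(T, S, A)` tables from [true_q_tables()].
#' @param discount discount factor.
#' @param behavior_model_prob optional vector of modeled behavior
#'   probabilities \eqn{\hat\pi_b(a_t|s_t)} per step.
#' @return Tibble with one row per step.
#' @export
dw_diagnostics <- function(traj, model, true_q = NULL, discount = 1,
                           behavior_model_prob = NULL) {
  stopifnot(length(unique(traj$subject_id)) == 1)
  traj <- dplyr::arrange(traj, .data$t)
  T_ <- nrow(traj)
  tt <- seq_len(T_)
  d <- discount^(tt - 1)
  qh <- if (length(dim(model$Qhat)) == 3) {
    model$Qhat[cbind(tt, traj$state, traj$action)]
  } else {
    model$Qhat[cbind(traj$state, traj$action)]
  }
  qh_means <- cumsum(qh * d) / tt
  if (is.null(true_q)) {
    q_true <- rep(NA_real_, T_)
  } else {
    q_true <- true_q[cbind(tt, traj$state, traj$action)]
  }
  delta <- qh - q_true
  delta_means <- cumsum(ifelse(is.na(delta), 0, delta) * d) / tt
  if (is.null(true_q)) delta_means <- rep(NA_real_, T_)
  q_means_true <- cumsum(ifelse(is.na(q_true), 0, q_true) * d) / tt
  if (is.null(true_q)) q_means_true <- rep(NA_real_, T_)
  phi <- c(NA_real_, vapply(
    2:T_,
    function(i) d[i] - sum(d[1:i]) / (i - 1), numeric(1)
  ))[seq_len(T_)]
  vback <- numeric(T_)
  vback[1] <- traj$reward[1]
  if (T_ > 1) {
    for (i in 2:T_) vback[i] <- discount * vback[i - 1] + traj$reward[i]
  }
  db <- if (is.null(behavior_model_prob)) {
    rep(0, T_)
  } else {
    1 - traj$behavior_prob / behavior_model_prob
  }
  tibble::tibble(
    t = traj$t, q_hat = qh, q_hat_means = qh_means,
    delta = delta, delta1 = q_true - q_means_true,
    delta2 = delta - delta_means, delta_means = delta_means,
    phi = phi, v_back = vback, behavior_mismatch = db
  )
}

#' Bias upper bound of the dueling-weight estimator
#'
#' The DW bias grows at most linearly in the horizon:
#' \eqn{|Bias| \le T \cdot r_{max}} where \eqn{r_{max}} is the maximum
#' positive per-step reward.
#'
#' @param horizon trajectory length T.
#' @param r_max maximum positive reward magnitude.
#' @return The bound `horizon * r_max`.
#' @export
dw_bias_bound <- function(horizon, r_max) {
  stopifnot(r_max >= 0, horizon >= 0)
  horizon * r_max
}

# ---- benchmark harness ----------------------------------------------------

#' The package's default off-policy evaluation benchmark
#'
#' A fixed randomized tabular MDP (rewards in \[-1, 1\], mildly sparse
#' transitions) paired with the policy regime the estimator suite targets in
#' application: a deterministic evaluation policy (a learned greedy
#' treatment policy is deterministic) logged under a stochastic behavior
#' policy that takes the evaluated action 60% of the time and explores
#' uniformly otherwise. The construction is fully determined by `seed`, so
#' the object behaves like a named reference dataset.
#'
#' @param horizon evaluation horizon T (default 20, the long-horizon
#'   setting).
#' @param n_states,n_actions state/action space sizes.
#' @param discount discount factor (default 0.99, near-undiscounted).
#' @param mix uniform-exploration mass of the behavior policy.
#' @param seed constructing seed.
#' @return List with `mdp`, `eval_policy`, `behavior_policy`.
#' @export
default_ope_benchmark <- function(horizon = 20, n_states = 8, n_actions = 4,
                                  discount = 0.99, mix = 0.4,
                                  seed = 20240902) {
  with_seed(as.integer(seed), {
    S <- n_states
    A <- n_actions
    P <- array(stats::rgamma(S * A * S, 1), c(S, A, S))
    P <- P / rep(apply(P, c(1, 2), sum), times = S)
    R <- matrix(stats::runif(S * A, -1, 1), S, A)
    mu <- stats::rgamma(S, 1)
    mdp <- tabular_mdp(P, R, mu / sum(mu), discount, horizon)
    pe <- deterministic_policy(max.col(R, ties.method = "first"), A)
    pb <- policy_table((1 - mix) * unclass(pe) + mix / A)
    list(mdp = mdp, eval_policy = pe, behavior_policy = pb)
  })
}

#' Replicated bias/variance benchmark of the estimator suite
#'
#' Repeatedly samples `n` trajectories from the behavior policy of an exact
#' tabular MDP, fits a value model per replicate, runs every estimator, and
#' summarizes bias (mean estimate minus the exact dynamic-programming value),
#' variance and mean squared error across replicates.
#'
#' @param mdp a [tabular_mdp()] with exactly computable value.
#' @param eval_policy,behavior_policy `(S, A)` policy matrices.
#' @param n trajectories per replicate.
#' @param replicates number of replicates.
#' @param seed integer seed governing the whole run.
#' @param estimators subset of
#'   `c("IS", "step-WIS", "DR", "WDR", "DW", "DWDR")`.
#' @param model_method passed to [fit_value_model()]; `"perfect"` uses the
#'   exact Bellman tables instead of a fit.
#' @param model_sweeps value-iteration sweeps for the fitted model.
#' @return A tibble (class `ope_benchmark`) with one row per estimator and
#'   columns `estimator`, `mean`, `bias`, `variance`, `mse`; the per-replicate
#'   estimate matrix is attached as attribute `"estimates"` and the exact
#'   value as `"exact"`.
#' @export
run_estimator_benchmark <- function(mdp, eval_policy, behavior_policy, n,
                                    replicates, seed,
                                    estimators = c(
                                      "IS", "step-WIS", "DR", "WDR",
                                      "DW", "DWDR"
                                    ),
                                    model_method = "dp", model_sweeps = 50) {
  eval_policy <- check_mdp_policy(mdp, eval_policy)
  behavior_policy <- check_mdp_policy(mdp, behavior_policy)
  exact <- evaluate_policy_exact(mdp, eval_policy)$value
  gamma <- mdp$discount
  est <- matrix(NA_real_, replicates, length(estimators),
    dimnames = list(NULL, estimators)
  )
  with_seed(as.integer(seed), {
    perfect <- if (model_method == "perfect") {
      perfect_value_model(mdp, eval_policy)
    } else {
      NULL
    }
    for (rep_i in seq_len(replicates)) {
      m <- sample_traj_mats(mdp, behavior_policy, n)
      rat <- ratio_mats(m, eval_policy, NULL)
      model <- if (model_method == "perfect") {
        perfect
      } else {
        fit_value_model(
          traj_mats_to_tibble(m), eval_policy,
          mdp$n_states, mdp$n_actions, gamma,
          method = model_method, sweeps = model_sweeps, quiet = TRUE
        )
      }
      for (e in estimators) {
        # horizon-collapse warnings (all cumulative ratios zero at a late
        # step) are expected under near-deterministic evaluation policies
        v <- suppressWarnings(switch(e,
          "IS" = core_is(m, rat, gamma),
          "step-WIS" = core_wis(m, rat, gamma),
          "DR" = core_dr(m, rat, model, gamma),
          "WDR" = core_wdr(m, rat, model, gamma),
          "DW" = core_dw(m, rat, model, gamma),
          "DWDR" = core_dwdr(m, rat, model, gamma),
          stop("unknown estimator: ", e)
        ))
        est[rep_i, e] <- mean(v)
      }
    }
  })
  if (replicates == 1) {
    warning("replicates = 1: variance reported as 0 by convention")
  }
  out <- tibble::tibble(
    estimator = estimators,
    mean = colMeans(est),
    bias = colMeans(est) - exact,
    variance = if (replicates > 1) apply(est, 2, stats::var) else rep(0, length(estimators)),
    mse = colMeans((est - exact)^2)
  )
  attr(out, "estimates") <- est
  attr(out, "exact") <- exact
  class(out) <- c("ope_benchmark", class(out))
  out
}

#' @export
autoplot.ope_benchmark <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("estimator", "bias", "variance", "mse")],
    -"estimator",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimator, y = .data$value,
    fill = .data$estimator
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Off-policy estimator benchmark")
}
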