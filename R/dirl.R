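#' Configuration of the inverse-RL policy learner
#'
#' Defaults: two hidden layers of 20 units, replay memory of 200
#' transitions, batches of 32, 100 episodes of 2000 transitions, and weight
#' step size 0.1. Examples and tests use scaled-down
#' `episodes`/`transitions_per_episode`.
#'
#' @param reward_spec the [reward_spec()] whose weights are learned.
#' @param learning_rate_q RMSProp step size for the Q-network.
#' @param learning_rate_w ascent step size for the reward weights
#'   (default 0.1).
#' @param memory_size replay capacity in transitions (default 200).
#' @param batch_size minibatch size (default 32).
#' @param episodes,transitions_per_episode training schedule (defaults 100
#'   and 2000); one reward-weight update is taken per episode.
#' @param discount discount factor.
#' @param seed integer seed; training is fully reproducible given the seed.
#' @param hidden_sizes hidden layer widths.
#' @param target_sync_period target-network synchronization period in
#'   update steps.
#' @param irl_temperature softmax temperature of the demonstration
#'   likelihood.
#' @param demo_batch_size demonstrations per weight update.
#' @param weight_cap reward weights are clipped into `[-cap, cap]` with a
#'   warning if an update diverges.
#' @param weight_average_window the reported final weights are the average
#'   of the last this-many episode iterates (tail averaging smooths the
#'   stochastic-ascent noise); 1 reports the last iterate.
#' @param prior_sd optional Gaussian prior standard deviation on the weights
#'   (maximum a posteriori variant); `NULL` for plain maximum likelihood.
#' @param initial_weights starting [reward_weights()] (default all 1).
#' @return A `dirl_config` object.
#' @export
dirl_config <- function(reward_spec = sepsisrl::reward_spec("sepsis_all"),
                        learning_rate_q = 1e-3, learning_rate_w = 0.1,
                        memory_size = 200, batch_size = 32,
                        episodes = 100, transitions_per_episode = 2000,
                        discount = 0.99, seed = 1,
                        hidden_sizes = c(20, 20), target_sync_period = 100,
                        irl_temperature = 0.5, demo_batch_size = 256,
                        weight_cap = 10, prior_sd = NULL,
                        weight_average_window = 10,
                        initial_weights = reward_weights()) {
  stopifnot(
    memory_size >= 1, batch_size >= 1, episodes >= 0,
    transitions_per_episode >= 0, discount >= 0, discount <= 1
  )
  structure(
    list(
      reward_spec = reward_spec, learning_rate_q = learning_rate_q,
      learning_rate_w = learning_rate_w, memory_size = as.integer(memory_size),
      batch_size = as.integer(batch_size), episodes = as.integer(episodes),
      transitions_per_episode = as.integer(transitions_per_episode),
      discount = discount, seed = as.integer(seed),
      hidden_sizes = hidden_sizes,
      target_sync_period = as.integer(target_sync_period),
      irl_temperature = irl_temperature,
      demo_batch_size = as.integer(demo_batch_size),
      weight_cap = weight_cap, prior_sd = prior_sd,
      weight_average_window = as.integer(weight_average_window),
      initial_weights = initial_weights
    ),
    class = "dirl_config"
  )
}

# Flatten a cohort into a transition store for offline training:
# standardized state/next-state matrices, 1-based flat actions, tanh-delta
# feature matrix (rewards are linear in the weights through it), terminal
# flags.
cohort_transitions <- function(cohort) {
  feats <- sepsis_features()
  miss <- setdiff(feats, names(cohort))
  if (length(miss)) stop("cohort lacks features: ", paste(miss, collapse = ", "))
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$t)
  fx <- as.matrix(cohort[, feats])
  step <- !is.na(cohort$action)
  nxt_same <- c(cohort$subject_id[-1] == cohort$subject_id[-nrow(cohort)], FALSE)
  if (!all(nxt_same[step])) stop("non-terminal step without a successor row")
  i_step <- which(step)
  # terminal transition: the successor row is the patient's last
  succ_is_last <- !step[i_step + 1L]
  withf <- tanh_delta_features(cohort)
  mu <- colMeans(fx[i_step, , drop = FALSE])
  sd <- apply(fx[i_step, , drop = FALSE], 2, stats::sd)
  sd[sd < 1e-8] <- 1
  std <- function(m) sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  # previous action within the same stay (baseline 0 at admission)
  act <- as.integer(cohort$action)
  prev <- c(NA_integer_, act[-nrow(cohort)])
  first_row <- c(TRUE, cohort$subject_id[-1] != cohort$subject_id[-nrow(cohort)])
  prev[first_row] <- NA_integer_
  list(
    state = std(fx[i_step, , drop = FALSE]),
    next_state = std(fx[i_step + 1L, , drop = FALSE]),
    action = act[i_step] + 1L,
    prev_action = ifelse(is.na(prev[i_step]), 0L, prev[i_step] + 1L),
    features = as.matrix(withf[, paste0("f", 0:5)]),
    terminal = succ_is_last,
    n = length(i_step),
    center = mu, scale = sd
  )
}

# State-adjusted per-action tanh-delta feature profile (25 x 6): each
# feature is regressed on the standardized state plus action dummies; the
# action coefficients isolate the dose response from severity-driven
# confounding (sicker patients receive different doses AND revert
# differently). Unseen actions fall back to 0 (the baseline action effect).
action_feature_profile <- function(trans, n_actions = 25) {
  a <- factor(trans$action, levels = seq_len(n_actions))
  D <- stats::model.matrix(~ a - 1)[, -1, drop = FALSE] # action 1 = baseline
  # indicator deltas respond to dose *changes*, so the previous hour's dose
  # is a confounder of the current action's effect; adjust for it
  Dprev <- if (!is.null(trans$prev_action)) {
    ap <- factor(trans$prev_action, levels = 0:n_actions)
    stats::model.matrix(~ ap - 1)[, -1, drop = FALSE]
  } else {
    NULL
  }
  X <- cbind(1, trans$state, Dprev, D)
  fit <- stats::lm.fit(X, trans$features)
  co <- fit$coefficients
  act_co <- co[(ncol(X) - ncol(D) + 1):ncol(X), , drop = FALSE]
  act_co[is.na(act_co)] <- 0
  psi <- rbind(0, act_co)
  rownames(psi) <- NULL
  # shrink sparsely observed action effects toward the baseline: a cell
  # logged a handful of times carries almost no dose-response information
  n_a <- tabulate(trans$action, n_actions)
  psi * (n_a / (n_a + 5))
}

#' One inverse-RL ascent step on the reward weights
#'
#' Maximum-likelihood inverse RL: clinician actions are modeled as Boltzmann
#' in the current Q-estimates, \eqn{\pi(a|s) \propto \exp(Q(s,a)/\tau)}, and
#' one ascent step is taken on the demonstration log-likelihood. The
#' gradient of Q with respect to the weights is approximated by the
#' per-action expected tanh-delta features `psi` (through which every
#' relabeled reward depends linearly on the weights), yielding the classic
#' observed-minus-expected feature difference
#' \deqn{\nabla_W \approx \frac{1}{B}\sum_b \psi(a_b) - E_{a \sim \pi(\cdot|s_b)} \psi(a).}
#' Only the spec's indicator subset is updated. With `prior_sd` set, a
#' Gaussian prior turns the step into maximum a posteriori ascent.
#'
#' @param weights current [reward_weights()].
#' @param demo_batch list with standardized `state` matrix and 1-based
#'   `action` vector of clinician demonstrations.
#' @param net the current [dueling_net()].
#' @param step_size ascent step size (0 leaves the weights unchanged).
#' @param spec a [reward_spec()]; indicators outside its index set are
#'   frozen.
#' @param psi `(n_actions, 6)` per-action expected tanh-delta features.
#' @param temperature softmax temperature \eqn{\tau}.
#' @param weight_cap clip bound; exceeding it warns and clips.
#' @param prior_sd optional Gaussian prior sd.
#' @return Updated [reward_weights()].
#' @export
update_reward_weights <- function(weights, demo_batch, net, step_size, spec,
                                  psi, temperature = 0.5, weight_cap = 10,
                                  prior_sd = NULL) {
  if (!nrow(demo_batch$state)) stop("empty demonstration batch")
  if (step_size == 0) return(weights)
  Q <- q_values(net, demo_batch$state) / temperature
  Q <- Q - apply(Q, 1, max)
  P <- exp(Q)
  P <- P / rowSums(P)
  obs <- psi[demo_batch$action, , drop = FALSE]
  expd <- P %*% psi
  grad <- colMeans(obs - expd)
  mask <- rep(0, 6)
  mask[spec$index_set + 1] <- 1
  grad <- grad * mask
  w <- as.numeric(weights)
  if (!is.null(prior_sd)) grad <- grad - mask * w / prior_sd^2
  w <- w + step_size * grad
  if (any(abs(w) > weight_cap)) {
    warning("reward weights exceeded the cap and were clipped")
    w <- clip(w, -weight_cap, weight_cap)
  }
  reward_weights(w)
}

#' Train the inverse-RL treatment policy
#'
#' Offline training on a fixed cohort: logged transitions are streamed in
#' random order through a bounded replay memory; every arrival triggers one
#' dueling double-DQN update on a sampled minibatch whose rewards are
#' computed from the current weight vector; after each episode one
#' inverse-RL ascent step updates the reward weights from a batch of
#' clinician demonstrations. Fully deterministic given `config$seed`.
#'
#' @param dataset a cohort step tibble (see [simulate_cohort()]).
#' @param config a [dirl_config()].
#' @return A `dirl_fit` with the trained `net`, learned `weights`, the
#'   per-episode `trace` (mean loss and weight history), feature
#'   standardization, and the greedy policy accessors [greedy_actions()].
#' @export
train_dirl <- function(dataset, config) {
  stopifnot(inherits(config, "dirl_config"), nrow(dataset) > 0)
  trans <- cohort_transitions(dataset)
  spec <- config$reward_spec
  wmask <- rep(0, 6)
  wmask[spec$index_set + 1] <- 1
  with_seed(config$seed, {
    net <- dueling_net(
      input_dim = ncol(trans$state), n_actions = 25,
      hidden_sizes = config$hidden_sizes,
      target_sync_period = config$target_sync_period
    )
    psi <- action_feature_profile(trans)
    w <- config$initial_weights
    n_ep <- config$episodes
    tpe <- config$transitions_per_episode
    losses <- numeric(0)
    ep_loss <- rep(NA_real_, n_ep)
    w_hist <- matrix(NA_real_, n_ep, 6, dimnames = list(NULL, names(w)))
    buffer <- integer(0)
    stream <- sample.int(trans$n)
    pos <- 0L
    if (n_ep > 0 && tpe > 0) {
      for (ep in seq_len(n_ep)) {
        ep_losses <- numeric(tpe)
        for (k in seq_len(tpe)) {
          pos <- pos + 1L
          if (pos > trans$n) {
            stream <- sample.int(trans$n)
            pos <- 1L
          }
          buffer <- c(buffer, stream[pos])
          if (length(buffer) > config$memory_size) {
            buffer <- buffer[-1L]
          }
          take <- sample(buffer, min(config$batch_size, length(buffer)))
          wv <- as.numeric(w) * wmask
          batch <- list(
            state = trans$state[take, , drop = FALSE],
            action = trans$action[take],
            reward = as.numeric(trans$features[take, , drop = FALSE] %*% wv),
            next_state = trans$next_state[take, , drop = FALSE],
            terminal = trans$terminal[take]
          )
          res <- dddqn_update_step(net, batch, config$discount,
            learning_rate = config$learning_rate_q
          )
          net <- res$net
          ep_losses[k] <- res$loss
        }
        demo <- if (config$demo_batch_size >= trans$n) {
          seq_len(trans$n)
        } else {
          sample.int(trans$n, config$demo_batch_size)
        }
        w <- update_reward_weights(
          w, list(
            state = trans$state[demo, , drop = FALSE],
            action = trans$action[demo]
          ),
          net, config$learning_rate_w, spec, psi,
          temperature = config$irl_temperature,
          weight_cap = config$weight_cap, prior_sd = config$prior_sd
        )
        ep_loss[ep] <- mean(ep_losses)
        w_hist[ep, ] <- as.numeric(w)
        losses <- c(losses, ep_losses)
      }
    }
    win <- config$weight_average_window
    if (is.null(win) || is.na(win)) win <- 1L
    if (n_ep > 0 && tpe > 0 && win > 1) {
      keep <- max(1L, n_ep - win + 1L):n_ep
      w <- reward_weights(colMeans(w_hist[keep, , drop = FALSE]))
    }
    structure(
      list(
        net = net, weights = w, psi = psi,
        trace = tibble::tibble(
          episode = seq_len(n_ep),
          loss = ep_loss
        ) |> dplyr::bind_cols(tibble::as_tibble(w_hist)),
        losses = losses,
        center = trans$center, scale = trans$scale,
        config = config
      ),
      class = "dirl_fit"
    )
  })
}

#' Greedy actions of a trained policy
#'
#' Maps raw (unstandardized) 30-feature states through the trained network
#' and returns the greedy flat action index (0-based, grid convention).
#'
#' @param fit a [train_dirl()] fit.
#' @param states matrix or tibble of raw feature rows (30 columns in
#'   [sepsis_features()] order, or a cohort tibble carrying them).
#' @return Integer vector of flat actions in 0..24.
#' @export
greedy_actions <- function(fit, states) {
  if (is.data.frame(states)) states <- as.matrix(states[, sepsis_features()])
  X <- sweep(sweep(states, 2, fit$center, "-"), 2, fit$scale, "/")
  max.col(q_values(fit$net, X), ties.method = "first") - 1L
}

#' @export
print.dirl_fit <- function(x, ...) {
  cat(sprintf(
    "<dirl_fit> %s: %d episodes, final loss %.4g\n",
    x$config$reward_spec$name, nrow(x$trace),
    if (nrow(x$trace)) x$trace$loss[nrow(x$trace)] else NA
  ))
  cat("  weights:", paste(sprintf("%.3f", as.numeric(x$weights)), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.dirl_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"episode",
    names_to = "series", values_to = "value"
  )
}

#' @export
glance.dirl_fit <- function(x, ...) {
  tibble::tibble(
    reward_spec = x$config$reward_spec$name,
    episodes = nrow(x$trace),
    final_loss = if (nrow(x$trace)) x$trace$loss[nrow(x$trace)] else NA_real_,
    !!!stats::setNames(
      as.list(as.numeric(x$weights)),
      names(x$weights)
    )
  )
}

#' @export
autoplot.dirl_fit <- function(object, ...) {
  df <- tidy.dirl_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$episode, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(title = "DIRL training trace", y = NULL)
}
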