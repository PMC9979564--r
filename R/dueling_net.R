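#' Dueling double deep Q-network
#'
#' A small fully connected network with two streams sharing a trunk:
#' a scalar state-value head \eqn{V(s; \theta, \beta)} and an advantage head
#' \eqn{A(s, a; \theta, \alpha)}, combined as
#' \deqn{Q(s, a) = V(s) + A(s, a) - \frac{1}{|A|}\sum_{a'} A(s, a')}
#' (mean-centering makes the decomposition identifiable). A frozen target
#' copy \eqn{(\theta^-, \beta^-, \alpha^-)} is kept for double-Q targets and
#' synchronized to the online parameters every `target_sync_period` updates.
#'
#' @param input_dim number of state features.
#' @param n_actions number of discrete actions (25 for the treatment grid).
#' @param hidden_sizes hidden layer widths (default `c(20, 20)`).
#' @param target_sync_period updates between target synchronizations.
#' @param init `"he"` (scaled random, uses the current RNG stream) or
#'   `"zero"`.
#' @return A `dueling_net` object.
#' @export
dueling_net <- function(input_dim, n_actions = 25, hidden_sizes = c(20, 20),
                        target_sync_period = 100, init = c("he", "zero")) {
  init <- match.arg(init)
  stopifnot(length(hidden_sizes) >= 1)
  dims <- c(input_dim, hidden_sizes)
  mk <- function(nin, nout) {
    if (init == "zero") {
      matrix(0, nin, nout)
    } else {
      matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    }
  }
  params <- list(W = list(), b = list())
  for (i in seq_along(hidden_sizes)) {
    params$W[[i]] <- mk(dims[i], dims[i + 1])
    params$b[[i]] <- numeric(dims[i + 1])
  }
  h <- dims[length(dims)]
  # zero-initialized heads: Q starts identically 0, so early Boltzmann
  # action likelihoods are uniform instead of echoing initialization noise
  params$Wv <- matrix(0, h, 1)
  params$bv <- 0
  params$Wa <- matrix(0, h, n_actions)
  params$ba <- numeric(n_actions)
  structure(
    list(
      params = params, target = params,
      input_dim = input_dim, n_actions = n_actions,
      hidden_sizes = hidden_sizes,
      target_sync_period = target_sync_period,
      updates = 0L, opt = NULL
    ),
    class = "dueling_net"
  )
}

net_forward <- function(params, X) {
  hs <- list()
  H <- X
  for (i in seq_along(params$W)) {
    Z <- sweep(H %*% params$W[[i]], 2, params$b[[i]], "+")
    H <- pmax(Z, 0)
    hs[[i]] <- H
  }
  V <- as.numeric(H %*% params$Wv + params$bv)
  A <- sweep(H %*% params$Wa, 2, params$ba, "+")
  Ac <- A - rowMeans(A)
  list(hs = hs, V = V, A = Ac, A_raw = A, Q = Ac + V, X = X)
}

#' Q-values of a dueling network
#'
#' `q_values()` returns the full `(n, n_actions)` action-value matrix for a
#' batch of states; `q_estimate()` the value of specific state-action pairs.
#' Advantages are mean-centered, so for every state
#' \eqn{\sum_a A(s, a) = 0} and adding a constant to the value stream shifts
#' all Q-values equally without changing the greedy action.
#'
#' @param net a [dueling_net()].
#' @param states numeric matrix `(n, input_dim)` (a vector is treated as one
#'   state).
#' @param actions integer vector of 1-based action indices.
#' @param target use the target copy instead of the online parameters.
#' @return `q_values()`: matrix; `q_estimate()`: numeric vector.
#' @export
q_values <- function(net, states, target = FALSE) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (ncol(states) != net$input_dim) {
    stop(sprintf(
      "state dimension %d does not match network input %d",
      ncol(states), net$input_dim
    ))
  }
  net_forward(if (target) net$target else net$params, states)$Q
}

#' @rdname q_values
#' @export
q_estimate <- function(net, states, actions, target = FALSE) {
  Q <- q_values(net, states, target = target)
  Q[cbind(seq_len(nrow(Q)), actions)]
}

#' Double-DQN regression target
#'
#' \eqn{y = r + \gamma\, Q_{target}(s', \arg\max_a Q_{online}(s', a))};
#' for terminal transitions the target is the reward alone. Action selection
#' uses the online network and evaluation the target network — the double-Q
#' decoupling that counters maximization bias.
#'
#' @param net a [dueling_net()] (provides the online parameters and, by
#'   default, the target copy).
#' @param transitions list with `next_state` matrix, `reward` vector, and
#'   logical `terminal` vector.
#' @param discount discount factor.
#' @param target_net optional distinct network supplying the target
#'   parameters.
#' @return Numeric target vector.
#' @export
double_dqn_target <- function(net, transitions, discount, target_net = NULL) {
  s2 <- transitions$next_state
  if (is.null(dim(s2))) s2 <- matrix(s2, nrow = 1)
  q_on <- q_values(net, s2)
  a_star <- max.col(q_on, ties.method = "first")
  q_tar <- if (is.null(target_net)) {
    q_values(net, s2, target = TRUE)
  } else {
    q_values(target_net, s2)
  }
  boot <- q_tar[cbind(seq_len(nrow(q_tar)), a_star)]
  boot[transitions$terminal] <- 0
  transitions$reward + discount * boot
}

rmsprop_init <- function(params) lapply(params, function(p) {
  if (is.list(p)) lapply(p, function(q) q * 0) else p * 0
})

rmsprop_apply <- function(params, grads, cache, lr, rho = 0.9, eps = 1e-8) {
  upd <- function(p, g, c) {
    c2 <- rho * c + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(c2) + eps), c = c2)
  }
  for (nm in c("Wv", "bv", "Wa", "ba")) {
    r <- upd(params[[nm]], grads[[nm]], cache[[nm]])
    params[[nm]] <- r$p; cache[[nm]] <- r$c
  }
  for (i in seq_along(params$W)) {
    r <- upd(params$W[[i]], grads$W[[i]], cache$W[[i]])
    params$W[[i]] <- r$p; cache$W[[i]] <- r$c
    r <- upd(params$b[[i]], grads$b[[i]], cache$b[[i]])
    params$b[[i]] <- r$p; cache$b[[i]] <- r$c
  }
  list(params = params, cache = cache)
}

# backprop of mean((Q[chosen] - target)^2) through the dueling decomposition
net_gradients <- function(params, fwd, actions, targets) {
  n <- nrow(fwd$Q)
  nA <- ncol(fwd$Q)
  resid <- fwd$Q[cbind(seq_len(n), actions)] - targets
  g <- 2 * resid / n
  dV <- g
  dA <- matrix(0, n, nA)
  dA[cbind(seq_len(n), actions)] <- g
  dA <- dA - rowMeans(dA) # centering jacobian: subtract mean over actions
  Hlast <- fwd$hs[[length(fwd$hs)]]
  grads <- list(
    Wv = crossprod(Hlast, dV), bv = sum(dV),
    Wa = crossprod(Hlast, dA), ba = colSums(dA),
    W = vector("list", length(params$W)),
    b = vector("list", length(params$W))
  )
  dH <- dV %*% t(params$Wv) + dA %*% t(params$Wa)
  for (i in rev(seq_along(params$W))) {
    dZ <- dH * (fwd$hs[[i]] > 0)
    Hin <- if (i == 1) fwd$X else fwd$hs[[i - 1]]
    grads$W[[i]] <- crossprod(Hin, dZ)
    grads$b[[i]] <- colSums(dZ)
    if (i > 1) dH <- dZ %*% t(params$W[[i]])
  }
  grads
}

#' One dueling double-DQN gradient step
#'
#' Computes double-Q targets for a batch of transitions, takes one RMSProp
#' step on the mean squared error between estimated and target Q-values, and
#' synchronizes the target copy every `target_sync_period` updates. Returns
#' the pre-step loss.
#'
#' @param net a [dueling_net()].
#' @param batch list with `state` matrix, 1-based `action`, `reward`,
#'   `next_state` matrix, logical `terminal`.
#' @param discount discount factor.
#' @param learning_rate RMSProp step size.
#' @return List with the updated `net` and the scalar `loss`.
#' @export
dddqn_update_step <- function(net, batch, discount, learning_rate = 1e-3) {
  stopifnot(nrow(batch$state) >= 1)
  targets <- double_dqn_target(net, batch, discount)
  fwd <- net_forward(net$params, batch$state)
  resid <- fwd$Q[cbind(seq_len(nrow(batch$state)), batch$action)] - targets
  loss <- mean(resid^2)
  if (!is.finite(loss)) {
    stop(sprintf(
      "non-finite DDDQN loss at update %d (learning rate too large or degenerate rewards?)",
      net$updates + 1L
    ))
  }
  grads <- net_gradients(net$params, fwd, batch$action, targets)
  if (is.null(net$opt)) net$opt <- rmsprop_init(net$params)
  res <- rmsprop_apply(net$params, grads, net$opt, learning_rate)
  net$params <- res$params
  net$opt <- res$cache
  net$updates <- net$updates + 1L
  if (net$updates %% net$target_sync_period == 0) net$target <- net$params
  list(net = net, loss = loss)
}
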