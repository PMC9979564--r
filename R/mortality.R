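#' Patient-level train/test split
#'
#' Splits a cohort by patient (never by step, so no patient's rows leak
#' across the two sides).
#'
#' @param trajectories cohort or trajectory step tibble.
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @return List with `train` and `test` step tibbles.
#' @export
split_dataset <- function(trajectories, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  ids <- unique(trajectories$subject_id)
  if (length(ids) < 2) stop("need at least 2 patients to split")
  n_train <- round(fraction * length(ids))
  if (n_train < 1 || n_train >= length(ids)) {
    stop("fraction leaves one side of the split empty")
  }
  tr_ids <- with_seed(as.integer(seed), sample(ids, n_train))
  list(
    train = trajectories[trajectories$subject_id %in% tr_ids, , drop = FALSE],
    test = trajectories[!trajectories$subject_id %in% tr_ids, , drop = FALSE]
  )
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
  }
  centers
}

#' Cluster patient states with k-means++
#'
#' Standardizes the feature columns, seeds k-means with the k-means++
#' scheme, and refines with Lloyd iterations. The fitted model assigns any
#' new state to its nearest center.
#'
#' @param states matrix or tibble of state feature rows.
#' @param k number of clusters (default 300, a cohort-scale choice).
#' @param seed integer seed.
#' @param iter_max Lloyd iteration cap.
#' @return A `cluster_model` with `centers` (standardized space), `k`,
#'   `sse`, standardization vectors, and per-row `assignment`.
#' @export
cluster_states <- function(states, k = 300, seed = 1, iter_max = 30) {
  if (is.data.frame(states)) {
    states <- as.matrix(states[, intersect(sepsis_features(), names(states))])
  }
  X <- as.matrix(states)
  if (nrow(X) < k) stop("fewer states than clusters")
  if (nrow(unique(X)) < k) stop("fewer distinct states than clusters")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  fit <- with_seed(as.integer(seed), {
    init <- kmeanspp_centers(Xs, k)
    suppressWarnings(
      stats::kmeans(Xs, centers = init, iter.max = iter_max, algorithm = "Lloyd")
    )
  })
  structure(
    list(
      k = k, centers = fit$centers, sse = fit$tot.withinss,
      center = mu, scale = sd, assignment = fit$cluster
    ),
    class = "cluster_model"
  )
}

#' Assign states to fitted clusters
#'
#' @param model a [cluster_states()] model.
#' @param states new state rows (matrix or tibble).
#' @return Integer cluster ids in `1..k` (nearest center).
#' @export
assign_clusters <- function(model, states) {
  if (is.data.frame(states)) {
    states <- as.matrix(states[, intersect(sepsis_features(), names(states))])
  }
  X <- sweep(sweep(as.matrix(states), 2, model$center, "-"), 2, model$scale, "/")
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; argmin over centers
  cross <- X %*% t(model$centers)
  cn <- rowSums(model$centers^2)
  max.col(2 * cross - matrix(cn, nrow(X), model$k, byrow = TRUE),
    ties.method = "first"
  )
}

#' Sum-of-squared-errors curve over candidate cluster counts
#'
#' Fits [cluster_states()] for every k in the grid and reports the SSE
#' curve with a largest-drop knee suggestion. The final choice of k remains
#' with the analyst.
#'
#' @param states state rows.
#' @param k_grid candidate cluster counts.
#' @param seed integer seed.
#' @return Tibble with `k` and `sse`, the knee suggestion attached as
#'   attribute `"suggested_k"`.
#' @export
choose_k_by_sse <- function(states, k_grid, seed = 1) {
  stopifnot(length(k_grid) >= 1)
  k_grid <- sort(unique(as.integer(k_grid)))
  sse <- vapply(
    k_grid,
    function(k) cluster_states(states, k, seed = seed)$sse,
    numeric(1)
  )
  out <- tibble::tibble(k = k_grid, sse = sse)
  suggested <- if (length(k_grid) == 1) {
    k_grid
  } else {
    # knee: largest relative drop in SSE per added cluster
    drop <- -diff(sse) / pmax(diff(k_grid), 1)
    rel <- drop / pmax(utils::head(sse, -1), 1e-12)
    k_grid[which.max(rel) + 1L]
  }
  attr(out, "suggested_k") <- suggested
  out
}

#' Tabular SARSA over clustered states
#'
#' On-policy temporal-difference evaluation of the logged clinician behavior:
#' trajectories are visited in randomized order (breaking within-stay
#' correlation) and each observed transition
#' \eqn{(s_t, a_t, r_t, s_{t+1}, a_{t+1})} updates
#' \deqn{Q(c_t, a_t) \mathrel{+}= \alpha (r_t + \gamma Q(c_{t+1}, a_{t+1}) - Q(c_t, a_t))}
#' on the cluster id \eqn{c_t}; terminal successors bootstrap 0. Unvisited
#' (cluster, action) cells remain at the zero initialization and are counted
#' in the coverage attribute.
#'
#' @param train cohort step tibble (rewards present).
#' @param cluster_model a [cluster_states()] model.
#' @param discount discount factor.
#' @param step_size SARSA learning rate (default 0.1).
#' @param sweeps passes over the training trajectories (default 50).
#' @param seed integer seed for the trajectory order.
#' @param n_actions number of flat actions.
#' @return `(k, n_actions)` Q matrix with attribute `"coverage"` (fraction of
#'   visited cells).
#' @export
sarsa_q <- function(train, cluster_model, discount = 0.99, step_size = 0.1,
                    sweeps = 50, seed = 1, n_actions = 25) {
  if (!nrow(train)) stop("empty training set")
  train <- dplyr::arrange(train, .data$subject_id, .data$t)
  cl <- assign_clusters(cluster_model, train)
  step <- !is.na(train$action)
  i_step <- which(step)
  succ <- i_step + 1L
  terminal <- !step[succ]
  s <- cl[i_step]
  a <- as.integer(train$action[i_step]) + 1L
  r <- train$reward[i_step]
  s2 <- cl[succ]
  a2 <- ifelse(terminal, NA_integer_, as.integer(train$action[succ]) + 1L)
  # per-trajectory index ranges
  subj <- train$subject_id[i_step]
  traj <- split(seq_along(i_step), subj)
  Q <- matrix(0, cluster_model$k, n_actions)
  with_seed(as.integer(seed), {
    for (sw in seq_len(sweeps)) {
      for (ti in sample(length(traj))) {
        for (i in traj[[ti]]) {
          boot <- if (terminal[i]) 0 else Q[s2[i], a2[i]]
          Q[s[i], a[i]] <- Q[s[i], a[i]] +
            step_size * (r[i] + discount * boot - Q[s[i], a[i]])
        }
      }
    }
  })
  visited <- matrix(FALSE, cluster_model$k, n_actions)
  visited[cbind(s, a)] <- TRUE
  attr(Q, "coverage") <- mean(visited)
  Q
}

#' Mortality-versus-return calibration curve
#'
#' Every visited step of the held-out set contributes its Q-value
#' \eqn{Q(c_t, a_t)} and its trajectory's terminal death label (1 for every
#' step of a non-survivor's stay). Q-values are cut into equal-count buckets
#' and each bucket reports its mean Q and mean mortality; empty buckets are
#' dropped. An isotonic (nonincreasing in Q) smoothing of the bucket
#' mortalities is stored for interpolation; the raw buckets are always
#' retained.
#'
#' @param test held-out cohort step tibble.
#' @param cluster_model a [cluster_states()] model.
#' @param q_table `(k, n_actions)` Q matrix from [sarsa_q()].
#' @param n_buckets number of equal-count buckets (default 20).
#' @return A `mortality_curve`: tibble with `bucket_mean_q`,
#'   `bucket_mortality`, `bucket_mortality_iso`, `bucket_count`.
#' @export
build_mortality_curve <- function(test, cluster_model, q_table, n_buckets = 20) {
  if (!nrow(test)) stop("empty test set")
  steps <- test[!is.na(test$action), , drop = FALSE]
  if (length(unique(steps$died)) < 2) {
    stop("held-out set contains a single outcome class; no curve can be built")
  }
  cl <- assign_clusters(cluster_model, steps)
  q <- q_table[cbind(cl, as.integer(steps$action) + 1L)]
  lab <- as.numeric(steps$died)
  br <- unique(stats::quantile(q, probs = seq(0, 1, length.out = n_buckets + 1)))
  bucket <- cut(q, breaks = br, include.lowest = TRUE)
  mq <- tapply(q, bucket, mean)
  mm <- tapply(lab, bucket, mean)
  cnt <- tapply(lab, bucket, length)
  keep <- !is.na(mq) & cnt >= 1
  ord <- order(mq[keep])
  mq <- as.numeric(mq[keep])[ord]
  mm <- as.numeric(mm[keep])[ord]
  cnt <- as.integer(cnt[keep])[ord]
  # isotonic nonincreasing fit of mortality against mean Q
  iso <- stats::isoreg(mq, -mm)
  curve <- tibble::tibble(
    bucket_mean_q = mq, bucket_mortality = mm,
    bucket_mortality_iso = -iso$yf, bucket_count = cnt
  )
  class(curve) <- c("mortality_curve", class(curve))
  attr(curve, "steps") <- tibble::tibble(
    subject_id = steps$subject_id, q = q, died = lab
  )
  curve
}

#' @export
autoplot.mortality_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bucket_mean_q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$bucket_mortality)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bucket_mortality_iso)) +
    ggplot2::labs(
      x = "mean Q (expected return)", y = "mortality",
      title = "Mortality versus expected return"
    )
}

#' Map an estimated return to a mortality estimate
#'
#' Piecewise-linear interpolation of the (isotonic by default) calibration
#' curve at the supplied return, clamped to the observed Q range (with a
#' warning) rather than extrapolating. The confidence interval is a
#' percentile bootstrap over held-out patients: each resample rebuilds the
#' bucket curve and re-reads the mortality at the same return.
#'
#' @param curve a [build_mortality_curve()] curve.
#' @param return_estimate the estimated expected return to map.
#' @param bootstrap_reps bootstrap resamples (0 skips the interval).
#' @param level confidence level.
#' @param smoothed interpolate the isotonic curve (default) or raw buckets.
#' @param seed integer seed for the bootstrap.
#' @return List with `mortality`, `lower`, `upper`, `level`.
#' @export
estimate_policy_mortality <- function(curve, return_estimate,
                                      bootstrap_reps = 1000, level = 0.95,
                                      smoothed = TRUE, seed = 1) {
  stopifnot(nrow(curve) >= 1)
  ycol <- if (smoothed) curve$bucket_mortality_iso else curve$bucket_mortality
  rng <- range(curve$bucket_mean_q)
  x <- return_estimate
  if (x < rng[1] || x > rng[2]) {
    warning(sprintf(
      "return %.4g outside the calibrated range [%.4g, %.4g]; clamped",
      x, rng[1], rng[2]
    ))
    x <- clip(x, rng[1], rng[2])
  }
  interp <- function(mq, my, at) {
    if (length(mq) == 1) return(my)
    stats::approx(mq, my, xout = clip(at, min(mq), max(mq)),
      rule = 2, ties = mean
    )$y
  }
  est <- interp(curve$bucket_mean_q, ycol, x)
  lower <- upper <- NA_real_
  steps <- attr(curve, "steps")
  if (bootstrap_reps > 0 && !is.null(steps)) {
    ids <- unique(steps$subject_id)
    n_buckets <- nrow(curve)
    boots <- with_seed(as.integer(seed), {
      vapply(seq_len(bootstrap_reps), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        sub <- steps[steps$subject_id %in% take, ]
        # weight resampled patients by multiplicity
        mult <- table(take)
        wts <- as.numeric(mult[as.character(sub$subject_id)])
        br <- unique(stats::quantile(
          rep(sub$q, wts),
          probs = seq(0, 1, length.out = n_buckets + 1)
        ))
        qq <- rep(sub$q, wts)
        ll <- rep(sub$died, wts)
        bucket <- cut(qq, br, include.lowest = TRUE)
        mq <- as.numeric(tapply(qq, bucket, mean))
        mm <- as.numeric(tapply(ll, bucket, mean))
        ok <- !is.na(mq)
        mq <- mq[ok]; mm <- mm[ok]
        o <- order(mq)
        mq <- mq[o]; mm <- mm[o]
        if (smoothed && length(mq) > 1) mm <- -stats::isoreg(mq, -mm)$yf
        interp(mq, mm, x)
      }, numeric(1))
    })
    alpha <- (1 - level) / 2
    lower <- stats::quantile(boots, alpha, names = FALSE)
    upper <- stats::quantile(boots, 1 - alpha, names = FALSE)
  }
  list(
    mortality = clip(est, 0, 1), lower = lower, upper = upper, level = level
  )
}
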