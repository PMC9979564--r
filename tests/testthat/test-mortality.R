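# a degenerate cluster model sending every state to one cluster
one_cluster_model <- function(n_feat = 30) {
  structure(
    list(
      k = 1, centers = matrix(0, 1, n_feat),
      sse = 0, center = rep(0, n_feat), scale = rep(1, n_feat),
      assignment = NULL
    ),
    class = "cluster_model"
  )
}

# hand-built cohort-like step table: constant features, scripted actions
scripted_cohort <- function(actions_by_subject, died_by_subject, reward = 1) {
  feats <- sepsis_features()
  rows <- purrr::imap(actions_by_subject, function(a, i) {
    i <- as.integer(i)
    tibble::tibble(
      subject_id = i, t = seq_along(c(a, NA)) - 1L,
      action = c(a, NA), behavior_prob = c(rep(1, length(a)), NA),
      reward = c(rep(reward, length(a)), NA),
      died = died_by_subject[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  for (f in feats) out[[f]] <- 0
  out
}

test_that("dataset split is patient-level, disjoint and seeded", {
  co <- small_cohort(n = 10, horizon = 5)
  sp <- split_dataset(co, 0.8, seed = 3)
  expect_equal(length(unique(sp$train$subject_id)), 8)
  expect_equal(length(unique(sp$test$subject_id)), 2)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(co))
  sp2 <- split_dataset(co, 0.8, seed = 3)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_error(split_dataset(co, 1.2), "fraction")

  # split mortality rates agree within binomial noise at scale
  co2 <- small_cohort(n = 2000, horizon = 8, seed = 19)
  sp3 <- split_dataset(co2, 0.8, seed = 4)
  m <- function(x) mean(tapply(x$died, x$subject_id, any))
  p <- m(co2)
  se <- sqrt(p * (1 - p) * (1 / 1600 + 1 / 400))
  expect_lt(abs(m(sp3$train) - m(sp3$test)), 3 * se)
})

test_that("k-means++ clustering is exact on k distinct points and seeded", {
  set.seed(51)
  pts <- matrix(rnorm(5 * 4, sd = 5), 5, 4)
  cm <- cluster_states(pts, k = 5, seed = 1)
  expect_equal(cm$sse, 0, tolerance = 1e-20)
  expect_equal(sort(unique(cm$assignment)), 1:5)
  expect_error(cluster_states(pts[c(1, 1, 2, 2, 3), ], k = 5), "distinct")

  X <- matrix(rnorm(400 * 6), 400, 6)
  c1 <- cluster_states(X, k = 20, seed = 9)
  c2 <- cluster_states(X, k = 20, seed = 9)
  expect_identical(c1$centers, c2$centers)

  # assignment agrees with a brute-force nearest-center scan
  newX <- matrix(rnorm(50 * 6), 50, 6)
  got <- assign_clusters(c1, newX)
  Xs <- sweep(sweep(newX, 2, c1$center, "-"), 2, c1$scale, "/")
  brute <- apply(Xs, 1, function(x) {
    which.min(colSums((t(c1$centers) - x)^2))
  })
  expect_equal(got, unname(brute))
})

test_that("SSE decreases with k and the knee finds planted blobs", {
  co <- small_cohort(n = 60, horizon = 8)
  states <- co[, sepsis_features()]
  curve <- choose_k_by_sse(states, c(5, 10, 20, 40), seed = 2)
  expect_true(all(diff(curve$sse) <= 0))

  # three well-separated blobs: the knee lands at k = 3
  set.seed(52)
  blobs <- rbind(
    matrix(rnorm(200, 0, 0.3), 100, 2),
    matrix(rnorm(200, 8, 0.3), 100, 2),
    matrix(rnorm(200, -8, 0.3) + rep(c(0, 16), each = 100), 100, 2)
  )
  kn <- choose_k_by_sse(blobs, 2:6, seed = 2)
  expect_equal(attr(kn, "suggested_k"), 3)
  single <- choose_k_by_sse(blobs, 4, seed = 2)
  expect_equal(attr(single, "suggested_k"), 4)
})

test_that("SARSA hits closed-form fixed points on degenerate chains", {
  cm <- one_cluster_model()
  # zero rewards leave the zero initialization untouched
  co0 <- scripted_cohort(list(rep(0L, 6), rep(0L, 6)), c(FALSE, FALSE), reward = 0)
  q0 <- sarsa_q(co0, cm, discount = 1, sweeps = 5, seed = 1)
  expect_equal(as.numeric(q0), rep(0, 25))

  # discount 0: Q converges to the mean one-step reward
  co1 <- scripted_cohort(list(rep(0L, 8), rep(0L, 8)), c(FALSE, FALSE), reward = 2)
  q1 <- sarsa_q(co1, cm, discount = 0, step_size = 0.3, sweeps = 80, seed = 1)
  expect_equal(q1[1, 1], 2, tolerance = 1e-3)

  # gamma = 1 aggregated chain of length T: the temporal-difference fixed
  # point solves Q = r + (1 - 1/T) Q, i.e. Q = r T
  T_ <- 6
  co2 <- scripted_cohort(list(rep(0L, T_), rep(0L, T_)), c(FALSE, FALSE), reward = 1)
  q2 <- sarsa_q(co2, cm, discount = 1, step_size = 0.05, sweeps = 600, seed = 1)
  expect_equal(q2[1, 1], T_, tolerance = 0.25)

  q2b <- sarsa_q(co2, cm, discount = 1, step_size = 0.05, sweeps = 600, seed = 1)
  expect_identical(q2, q2b)
  expect_equal(attr(q2, "coverage"), 1 / 25)
})

test_that("mortality curve buckets conserve steps and split trivial labels", {
  cm <- one_cluster_model()
  # deaths always act low-Q (action 0), survivors act high-Q (action 1)
  co <- scripted_cohort(
    c(replicate(6, rep(0L, 5), simplify = FALSE),
      replicate(6, rep(1L, 5), simplify = FALSE)),
    rep(c(TRUE, FALSE), each = 6)
  )
  qtab <- matrix(0, 1, 25)
  qtab[1, 2] <- 10
  curve <- build_mortality_curve(co, cm, qtab, n_buckets = 2)
  expect_equal(curve$bucket_mortality, c(1, 0))
  expect_equal(sum(curve$bucket_count), sum(!is.na(co$action)))
  expect_true(all(diff(curve$bucket_mortality_iso) <= 1e-12))
  co_onelabel <- dplyr::mutate(co, died = TRUE)
  expect_error(build_mortality_curve(co_onelabel, cm, qtab), "single outcome")
})

test_that("mortality mapping interpolates knots, clamps, and bounds", {
  curve <- tibble::tibble(
    bucket_mean_q = c(-1, 0, 1, 2),
    bucket_mortality = c(0.5, 0.3, 0.25, 0.05),
    bucket_mortality_iso = c(0.5, 0.3, 0.25, 0.05),
    bucket_count = c(10L, 10L, 10L, 10L)
  )
  class(curve) <- c("mortality_curve", class(curve))
  # knot evaluation returns the bucket's own mortality
  for (i in 1:4) {
    expect_equal(
      estimate_policy_mortality(curve, curve$bucket_mean_q[i],
        bootstrap_reps = 0
      )$mortality,
      curve$bucket_mortality[i]
    )
  }
  expect_equal(
    estimate_policy_mortality(curve, 0.5, bootstrap_reps = 0)$mortality,
    0.275
  )
  expect_warning(
    out <- estimate_policy_mortality(curve, 99, bootstrap_reps = 0),
    "clamped"
  )
  expect_equal(out$mortality, 0.05)
  expect_true(out$mortality >= 0 && out$mortality <= 1)
})

test_that("behavior return maps back to the cohort's own mortality", {
  co <- small_cohort(n = 900, horizon = 14, seed = 23)
  sp <- split_dataset(co, 0.8, seed = 1)
  cm <- cluster_states(sp$train, k = 60, seed = 2)
  qtab <- sarsa_q(sp$train, cm, discount = 0.99, sweeps = 15, seed = 3)
  curve <- build_mortality_curve(sp$test, cm, qtab, n_buckets = 12)
  tab <- sepsisrl:::cohort_to_tabular(sp$test, cm)
  pi_b <- sepsisrl:::behavior_policy_on_clusters(tab, cm$k)
  v_b <- estimate_dr(tab, pi_b, pi_b, discount = 0.99)$estimate
  est <- estimate_policy_mortality(curve, v_b, bootstrap_reps = 250, seed = 4)
  emp <- mean(tapply(sp$test$died, sp$test$subject_id, any))
  expect_gte(emp, est$lower - 1e-9)
  expect_lte(emp, est$upper + 1e-9)
})
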