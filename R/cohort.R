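#' The 30 state features of the synthetic ICU cohort
#'
#' The simulator emits states with 30 named features spanning demographics,
#' vital signs and laboratory values, including the six reward indicators
#' (QSOFA, SOFA, MAP, lactate, PaO2, PT). The set is a documented stand-in
#' for a typical sepsis feature extraction; no canonical 30-feature list
#' exists for this problem.
#'
#' @return `sepsis_features()`: character vector of 30 feature names;
#'   `sepsis_feature_table()`: tibble with `feature` and `unit`.
#' @export
sepsis_features <- function() sepsis_feature_table()$feature

#' @rdname sepsis_features
#' @export
sepsis_feature_table <- function() {
  tibble::tribble(
    ~feature, ~unit,
    "age_years", "years",
    "gender_male", "0/1",
    "weight_kg", "kg",
    "heart_rate_bpm", "beats/min",
    "resp_rate_bpm", "breaths/min",
    "temp_celsius", "degC",
    "sbp_mmHg", "mmHg",
    "dbp_mmHg", "mmHg",
    "map_mmHg", "mmHg",
    "spo2_pct", "%",
    "gcs_score", "points",
    "qsofa_score", "points",
    "sofa_score", "points",
    "lactate_mmol_per_L", "mmol/L",
    "pao2_mmHg", "mmHg",
    "paco2_mmHg", "mmHg",
    "ph_arterial", "pH",
    "pt_seconds", "s",
    "ptt_seconds", "s",
    "inr", "ratio",
    "creatinine_mg_dL", "mg/dL",
    "bun_mg_dL", "mg/dL",
    "wbc_k_per_uL", "1000/uL",
    "platelets_k_per_uL", "1000/uL",
    "hemoglobin_g_dL", "g/dL",
    "sodium_mEq_L", "mEq/L",
    "potassium_mEq_L", "mEq/L",
    "chloride_mEq_L", "mEq/L",
    "glucose_mg_dL", "mg/dL",
    "bicarbonate_mEq_L", "mEq/L"
  )
}

# Rough reference value, scale and adverse direction per feature, used to
# express per-step death hazard in standardized "adverse deviation" units for
# any choice of planted mortality drivers.
feature_hazard_table <- function() {
  tibble::tribble(
    ~feature, ~ref, ~scale, ~direction,
    "age_years", 62, 16, 1,
    "gender_male", 0.5, 1, 0,
    "weight_kg", 80, 18, 0,
    "heart_rate_bpm", 86, 12, 1,
    "resp_rate_bpm", 19, 4, 1,
    "temp_celsius", 37, 0.8, 1,
    "sbp_mmHg", 118, 18, -1,
    "dbp_mmHg", 62, 12, -1,
    "map_mmHg", 80, 12, -1,
    "spo2_pct", 96, 3, -1,
    "gcs_score", 14, 3, -1,
    "qsofa_score", 1.3, 0.8, 1,
    "sofa_score", 6, 4, 1,
    "lactate_mmol_per_L", 1.8, 1.2, 1,
    "pao2_mmHg", 90, 15, -1,
    "paco2_mmHg", 40, 6, 1,
    "ph_arterial", 7.39, 0.06, -1,
    "pt_seconds", 14, 4, 1,
    "ptt_seconds", 30, 8, 1,
    "inr", 1.1, 0.4, 1,
    "creatinine_mg_dL", 1.0, 0.5, 1,
    "bun_mg_dL", 18, 9, 1,
    "wbc_k_per_uL", 10, 4, 1,
    "platelets_k_per_uL", 230, 60, -1,
    "hemoglobin_g_dL", 11.5, 1.5, -1,
    "sodium_mEq_L", 139, 4, 0,
    "potassium_mEq_L", 4.1, 0.5, 1,
    "chloride_mEq_L", 104, 4, 0,
    "glucose_mg_dL", 135, 40, 1,
    "bicarbonate_mEq_L", 24, 3, -1
  )
}

#' Treatment action grid
#'
#' The 5 x 5 discretized treatment space over intravenous fluid rate and
#' vasopressor dose. `iv_edges`/`vp_edges` are the nondecreasing lower edges
#' of the five bins per axis; bin 0 is the zero dose and doses above the top
#' edge map to bin 4. The flat action index is `5 * iv_bin + vp_bin`
#' (0-based, in 0..24).
#'
#' @param iv_edges,vp_edges numeric length-5 nondecreasing lower bin edges,
#'   first edge 0.
#' @return An `action_grid` object.
#' @export
action_grid <- function(iv_edges, vp_edges) {
  for (e in list(iv_edges, vp_edges)) {
    if (length(e) != 5 || is.unsorted(e) || e[1] != 0) {
      stop("edges must be 5 nondecreasing values starting at the zero dose")
    }
  }
  structure(list(iv_edges = iv_edges, vp_edges = vp_edges),
    class = "action_grid"
  )
}

#' @rdname action_grid
#' @details The default edges approximate common quantile-based dose bins on
#'   a 1-hour grid: IV fluids in mL/h and vasopressor in norepinephrine-
#'   equivalent ug/kg/min.
#' @export
default_action_grid <- function() {
  action_grid(
    iv_edges = c(0, 20, 80, 200, 500),
    vp_edges = c(0, 0.05, 0.15, 0.30, 0.50)
  )
}

#' Discretize continuous doses onto the action grid
#'
#' @param iv_dose,vp_dose nonnegative dose vectors.
#' @param grid an [action_grid()].
#' @return Tibble with `iv_bin`, `vp_bin` (0-based) and flat `action`.
#' @export
discretize_action <- function(iv_dose, vp_dose, grid = default_action_grid()) {
  if (any(iv_dose < 0) || any(vp_dose < 0)) stop("doses must be nonnegative")
  # left-closed bins [e_k, e_{k+1}); doses above the top edge stay in bin 4
  bin <- function(x, edges) pmin(findInterval(x, edges) - 1L, 4L)
  ivb <- bin(iv_dose, grid$iv_edges)
  vpb <- bin(vp_dose, grid$vp_edges)
  tibble::tibble(iv_bin = ivb, vp_bin = vpb, action = 5L * ivb + vpb)
}

#' Action count table over the 5 x 5 grid
#'
#' Counts how often each (IV bin, VP bin) cell occurs across the non-terminal
#' steps of a cohort; the grand total equals the number of steps.
#'
#' @param trajectories cohort step tibble with a 0-based flat `action` column.
#' @return 5 x 5 integer matrix, rows = IV bins, columns = VP bins.
#' @export
summarize_action_distribution <- function(trajectories) {
  a <- trajectories$action
  a <- a[!is.na(a)]
  if (!length(a)) stop("no actions to summarize")
  if (any(a < 0 | a > 24)) stop("flat actions must lie in 0..24")
  counts <- matrix(tabulate(a + 1L, 25L), 5, 5, byrow = TRUE)
  dimnames(counts) <- list(iv_bin = 0:4, vp_bin = 0:4)
  counts
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients.
#' @param horizon maximum stay length in hours (1-hour decision grid).
#' @param target_mortality cohort mortality rate the per-step death hazard is
#'   calibrated to (default 0.145, emulating a typical adult sepsis cohort).
#' @param behavior_temperature softmax temperature of the clinician-like
#'   behavior policy; lower is greedier.
#' @param behavior_epsilon practice-variation floor: fraction of uniformly
#'   random dosing mixed into the behavior policy so every grid cell retains
#'   support.
#' @param planted_mortality_drivers two (or more) feature names whose adverse
#'   deviations dominate the death hazard.
#' @param seed integer seed.
#' @param behavior_reward_weights optional [reward_weights()]: when supplied,
#'   the behavior policy is Boltzmann in the expected one-step reward under
#'   these weights (demonstration mode for inverse-RL recovery experiments)
#'   instead of the severity-guided clinician profile.
#' @param behavior_reward_spec reward spec used in demonstration mode.
#' @param reward_label_weights weights used to fill the cohort's `reward`
#'   column (default: clinically signed — improvements in every indicator
#'   are positive, so lactate and PT increases score negatively).
#' @param driver_coef hazard log-odds coefficient per standardized adverse
#'   driver deviation.
#' @param severity_coef hazard log-odds coefficient on latent severity
#'   (background risk not attributable to the planted drivers).
#' @param hazard_intercept optional fixed hazard intercept; when `NULL` it is
#'   calibrated to `target_mortality` by bisection against pilot simulations.
#' @param discharge_threshold latent-severity level below which a stabilized
#'   patient is discharged alive before the horizon (set to `-Inf` to keep
#'   everyone until the horizon).
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients, horizon = 24, target_mortality = 0.145,
                          behavior_temperature = 0.7,
                          behavior_epsilon = 0.02,
                          planted_mortality_drivers = c("pao2_mmHg", "pt_seconds"),
                          seed = 1,
                          behavior_reward_weights = NULL,
                          behavior_reward_spec = reward_spec("sepsis_all"),
                          reward_label_weights = reward_weights(c(1, 1, 1, -1, 1, -1)),
                          driver_coef = 3.0, severity_coef = 0,
                          hazard_intercept = NULL,
                          discharge_threshold = 0.3) {
  stopifnot(
    n_patients >= 1, horizon >= 2,
    target_mortality > 0, target_mortality < 1,
    behavior_temperature > 0,
    behavior_epsilon >= 0, behavior_epsilon < 1
  )
  unknown <- setdiff(planted_mortality_drivers, sepsis_features())
  if (length(unknown)) {
    stop("unknown mortality drivers: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(
      n_patients = as.integer(n_patients), horizon = as.integer(horizon),
      target_mortality = target_mortality,
      behavior_temperature = behavior_temperature,
      behavior_epsilon = behavior_epsilon,
      planted_mortality_drivers = planted_mortality_drivers,
      seed = as.integer(seed),
      behavior_reward_weights = behavior_reward_weights,
      behavior_reward_spec = behavior_reward_spec,
      reward_label_weights = reward_label_weights,
      driver_coef = driver_coef, severity_coef = severity_coef,
      hazard_intercept = hazard_intercept,
      discharge_threshold = discharge_threshold
    ),
    class = "cohort_config"
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic (noise-free) means of the six indicator features given the
# latent state (reversible severity z, progressive lung damage d1,
# coagulopathy d2) and the previous hour's dose bins. Shared by the emission
# model and the expected-delta scoring of reward-guided behavior.
indicator_means <- function(lat, iv_prev, vp_prev) {
  over_iv <- pmax(iv_prev - 2, 0)
  over_vp <- pmax(vp_prev - 2, 0)
  z <- lat$z
  cbind(
    qsofa_score = clip(1.3 + 0.7 * z, 0, 3),
    sofa_score = clip(6 + 2.6 * z, 0, 24),
    map_mmHg = clip(82 - 9 * z + 1.6 * vp_prev, 20, 180),
    lactate_mmol_per_L = clip(1.8 + 1.0 * z - 0.12 * iv_prev, 0.2, 25),
    # moderate pressor support aids oxygen delivery; high doses constrict
    # and volume overload congests the lungs; accumulated lung injury (d1)
    # erodes oxygenation irreversibly
    pao2_mmHg = clip(
      96 - 1.0 * z - 12 * lat$d1 + 0.4 * vp_prev - 0.8 * over_vp -
        2.4 * over_iv, 30, 400
    ),
    # progressive coagulopathy (d2) and dilution from aggressive volume
    # loading both lengthen PT
    pt_seconds = clip(13.5 + 0.4 * z + 3.2 * lat$d2 + 3.4 * over_iv, 8, 120)
  )
}

# Full 30-feature emission with observation noise. statics: matrix with
# columns age_years, gender_male, weight_kg.
emit_features <- function(lat, iv_prev, vp_prev, statics) {
  z <- lat$z
  n <- length(z)
  ind <- indicator_means(lat, iv_prev, vp_prev)
  map <- clip(ind[, "map_mmHg"] + stats::rnorm(n, 0, 4), 20, 180)
  pao2 <- clip(ind[, "pao2_mmHg"] + stats::rnorm(n, 0, 3), 30, 400)
  coag <- 0.25 * z + lat$d2
  out <- cbind(
    age_years = statics[, 1],
    gender_male = statics[, 2],
    weight_kg = statics[, 3],
    heart_rate_bpm = clip(86 + 9 * z + stats::rnorm(n, 0, 6), 30, 220),
    resp_rate_bpm = clip(19 + 3 * z + stats::rnorm(n, 0, 2.5), 5, 60),
    temp_celsius = clip(37 + 0.4 * z + stats::rnorm(n, 0, 0.4), 32, 42.5),
    sbp_mmHg = clip(1.45 * map + 8 + stats::rnorm(n, 0, 5), 40, 260),
    dbp_mmHg = clip(0.75 * map - 4 + stats::rnorm(n, 0, 4), 20, 160),
    map_mmHg = map,
    spo2_pct = clip(
      97 - 1.5 * z + 0.008 * (pao2 - 90) + stats::rnorm(n, 0, 1.6), 50, 100
    ),
    gcs_score = clip(round(14.5 - 1.6 * z + stats::rnorm(n, 0, 0.8)), 3, 15),
    qsofa_score = clip(round(ind[, "qsofa_score"] + stats::rnorm(n, 0, 0.35)), 0, 3),
    sofa_score = clip(round(ind[, "sofa_score"] + stats::rnorm(n, 0, 2.2)), 0, 24),
    lactate_mmol_per_L = clip(
      ind[, "lactate_mmol_per_L"] + stats::rnorm(n, 0, 0.5), 0.2, 25
    ),
    pao2_mmHg = pao2,
    paco2_mmHg = clip(40 + 2 * z + stats::rnorm(n, 0, 4), 15, 90),
    ph_arterial = clip(7.39 - 0.05 * z + stats::rnorm(n, 0, 0.03), 6.8, 7.7),
    pt_seconds = clip(ind[, "pt_seconds"] + stats::rnorm(n, 0, 0.7), 8, 120),
    ptt_seconds = clip(30 + 4 * coag + stats::rnorm(n, 0, 8), 15, 150),
    inr = clip(1.1 + 0.15 * coag + stats::rnorm(n, 0, 0.3), 0.8, 12),
    creatinine_mg_dL = clip(1.0 + 0.5 * z + stats::rnorm(n, 0, 0.25), 0.2, 15),
    bun_mg_dL = clip(18 + 7 * z + stats::rnorm(n, 0, 4), 2, 150),
    wbc_k_per_uL = clip(10 + 3 * z + stats::rnorm(n, 0, 2), 0.5, 80),
    platelets_k_per_uL = clip(230 - 35 * z + stats::rnorm(n, 0, 30), 5, 1000),
    hemoglobin_g_dL = clip(11.5 - 0.6 * z + stats::rnorm(n, 0, 0.8), 3, 20),
    sodium_mEq_L = clip(139 + stats::rnorm(n, 0, 3), 110, 175),
    potassium_mEq_L = clip(4.1 + 0.15 * z + stats::rnorm(n, 0, 0.3), 1.5, 9),
    chloride_mEq_L = clip(104 + stats::rnorm(n, 0, 3), 70, 140),
    glucose_mg_dL = clip(135 + 12 * z + stats::rnorm(n, 0, 25), 30, 1000),
    bicarbonate_mEq_L = clip(24 - 2 * z + stats::rnorm(n, 0, 2), 5, 50)
  )
  out[, sepsis_features(), drop = FALSE]
}

# Latent dynamics. Reversible severity z follows an AR(1) nudged by how
# well the dose matches the severity-appropriate target (with an overdose
# penalty); sustained high severity accrues irreversible organ damage at a
# patient-specific susceptibility (frailties f1: lung, f2: coagulation).
latent_update <- function(lat, iv, vp, noise_sd = 0.22) {
  z <- lat$z
  niv <- clip(round(1.1 * z + 0.6), 0, 4)
  nvp <- clip(round(0.9 * z + 0.3), 0, 4)
  help <- (4 - abs(iv - niv) - abs(vp - nvp)) / 4
  overdose <- (pmax(iv - niv, 0) + pmax(vp - nvp, 0)) / 4
  n <- length(z)
  # near-unit-root severity: treatment sets the drift (stabilize vs
  # deteriorate) rather than snapping the level back, so hourly gains do
  # not scale with how sick the patient currently is
  z2 <- 0.995 * z + 0.012 - 0.085 * help + 0.07 * overdose +
    (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  burden <- pmax(z2 - 1, 0)
  # organ damage accrues both with sustained severity and through an
  # idiosyncratic channel scaled by patient susceptibility, so the drivers
  # are not a pure readout of global severity
  d1 <- 0.99 * lat$d1 + 0.02 * burden * exp(1.1 * lat$f1) +
    (if (noise_sd > 0) abs(stats::rnorm(n, 0, 0.09)) * exp(0.8 * lat$f1) else 0)
  d2 <- 0.99 * lat$d2 + 0.02 * burden * exp(1.1 * lat$f2) +
    (if (noise_sd > 0) abs(stats::rnorm(n, 0, 0.09)) * exp(0.8 * lat$f2) else 0)
  list(z = z2, d1 = d1, d2 = d2, f1 = lat$f1, f2 = lat$f2)
}

lat_slice <- function(lat, idx) {
  list(
    z = lat$z[idx], d1 = lat$d1[idx], d2 = lat$d2[idx],
    f1 = lat$f1[idx], f2 = lat$f2[idx]
  )
}

# behavior action probabilities, n x 25 (flat index column j = action j-1)
behavior_probs <- function(lat, iv_prev, vp_prev, config) {
  z <- lat$z
  n <- length(z)
  ivg <- rep(0:4, each = 5)
  vpg <- rep(0:4, times = 5)
  if (is.null(config$behavior_reward_weights)) {
    niv <- clip(round(1.1 * z + 0.6), 0, 4)
    nvp <- clip(round(0.9 * z + 0.3), 0, 4)
    score <- -(outer(niv, ivg, "-")^2 + outer(nvp, vpg, "-")^2)
  } else {
    # demonstration mode: Boltzmann in the expected one-step reward
    score <- expected_reward_by_action(
      lat, iv_prev, vp_prev,
      config$behavior_reward_spec, config$behavior_reward_weights
    )
  }
  score <- score / config$behavior_temperature
  score <- score - apply(score, 1, max)
  p <- exp(score)
  p <- p / rowSums(p)
  eps <- config$behavior_epsilon
  if (is.null(eps)) eps <- 0
  (1 - eps) * p + eps / ncol(p)
}

# expected one-step reward of every action given current latent state;
# n x 25 matrix. Uses noise-free indicator means at the deterministic
# severity update.
expected_reward_by_action <- function(lat, iv_prev, vp_prev, spec, weights) {
  n <- length(lat$z)
  cur <- indicator_means(lat, iv_prev, vp_prev)
  w <- as.numeric(weights)
  out <- matrix(0, n, 25)
  for (iv in 0:4) {
    for (vp in 0:4) {
      lat2 <- latent_update(lat, rep(iv, n), rep(vp, n), noise_sd = 0)
      nxt <- indicator_means(lat2, rep(iv, n), rep(vp, n))
      deltas <- cbind(
        s0 = cur[, 1] - nxt[, 1], s1 = cur[, 2] - nxt[, 2],
        s2 = nxt[, 3] - cur[, 3], s3 = nxt[, 4] - cur[, 4],
        s4 = nxt[, 5] - cur[, 5], s5 = nxt[, 6] - cur[, 6]
      )
      r <- numeric(n)
      for (i in spec$index_set) r <- r + w[i + 1] * tanh(deltas[, i + 1])
      out[, 5L * iv + vp + 1L] <- r
    }
  }
  out
}

# per-step death hazard from the planted drivers + background severity
step_hazard <- function(feats, z, config, intercept) {
  ht <- feature_hazard_table()
  dev <- 0
  for (f in config$planted_mortality_drivers) {
    row <- ht[ht$feature == f, ]
    dev <- dev + row$direction * (feats[, f] - row$ref) / row$scale
  }
  stats::plogis(intercept + config$driver_coef * dev + config$severity_coef * z)
}

run_cohort_sim <- function(config, intercept, n_override = NULL) {
  n <- if (is.null(n_override)) config$n_patients else n_override
  H <- config$horizon
  statics <- cbind(
    clip(stats::rnorm(n, 62, 16), 18, 95),
    as.numeric(stats::runif(n) < 0.57),
    clip(stats::rnorm(n, 80, 18), 35, 180)
  )
  z0 <- stats::rnorm(n, 0.8, 0.9)
  f1 <- stats::rnorm(n)
  f2 <- stats::rnorm(n)
  lat <- list(
    z = z0,
    d1 = 0.35 * pmax(z0 - 1, 0) * exp(1.1 * f1),
    d2 = 0.35 * pmax(z0 - 1, 0) * exp(1.1 * f2),
    f1 = f1, f2 = f2
  )
  iv_prev <- integer(n)
  vp_prev <- integer(n)
  feats <- emit_features(lat, iv_prev, vp_prev, statics)
  alive <- rep(TRUE, n)
  died <- rep(FALSE, n)
  rows <- vector("list", H + 1L)
  for (t in seq_len(H)) {
    idx <- which(alive)
    if (!length(idx)) break
    p <- behavior_probs(
      lat_slice(lat, idx), iv_prev[idx], vp_prev[idx], config
    )
    u <- stats::runif(length(idx))
    cum <- p %*% upper.tri(diag(25), diag = TRUE) # row-wise cumulative sums
    act <- rowSums(cum < u) # 0-based flat action
    act[act > 24L] <- 24L
    bp <- p[cbind(seq_along(idx), act + 1L)]
    iv <- act %/% 5L
    vp <- act %% 5L
    rows[[t]] <- tibble::tibble(
      subject_id = idx, t = t - 1L,
      iv_bin = iv, vp_bin = vp, action = act,
      behavior_prob = bp, reward = NA_real_,
      tibble::as_tibble(feats[idx, , drop = FALSE])
    )
    new_lat <- latent_update(lat_slice(lat, idx), iv, vp)
    lat$z[idx] <- new_lat$z
    lat$d1[idx] <- new_lat$d1
    lat$d2[idx] <- new_lat$d2
    iv_prev[idx] <- iv
    vp_prev[idx] <- vp
    newf <- emit_features(new_lat, iv, vp, statics[idx, , drop = FALSE])
    feats[idx, ] <- newf
    h <- step_hazard(newf, new_lat$z, config, intercept)
    u_death <- stats::runif(length(idx))
    dead_now <- idx[u_death < h]
    thr <- config$discharge_threshold
    if (is.null(thr)) thr <- -Inf
    # discharge requires resolved severity AND near-normal organ function
    out_now <- idx[u_death >= h & new_lat$z < thr &
      new_lat$d1 < 0.5 & new_lat$d2 < 0.5]
    leaving <- c(dead_now, out_now)
    if (length(leaving)) {
      died[dead_now] <- TRUE
      alive[leaving] <- FALSE
      rows[[H + 1L]] <- dplyr::bind_rows(
        rows[[H + 1L]],
        tibble::tibble(
          subject_id = leaving, t = t,
          iv_bin = NA_integer_, vp_bin = NA_integer_, action = NA_integer_,
          behavior_prob = NA_real_, reward = NA_real_,
          tibble::as_tibble(feats[leaving, , drop = FALSE])
        )
      )
    }
  }
  idx <- which(alive)
  if (length(idx)) {
    rows[[H + 1L]] <- dplyr::bind_rows(
      rows[[H + 1L]],
      tibble::tibble(
        subject_id = idx, t = H,
        iv_bin = NA_integer_, vp_bin = NA_integer_, action = NA_integer_,
        behavior_prob = NA_real_, reward = NA_real_,
        tibble::as_tibble(feats[idx, , drop = FALSE])
      )
    )
  }
  cohort <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$subject_id, .data$t)
  cohort$died <- died[cohort$subject_id]
  cohort
}

#' Simulate a synthetic ICU sepsis cohort
#'
#' Generates patient trajectories on a 1-hour grid from a latent-severity
#' state-space model: scalar severity follows an AR(1) process nudged by how
#' well the chosen dose matches the severity-appropriate dose (with an
#' overdose penalty), 30 features are emitted around severity with
#' physiologic clipping, and a per-step logistic death hazard is dominated
#' by the adverse deviations of the planted mortality-driver features. The
#' clinician-like behavior policy is a softmax over a severity-responsive
#' dose preference whose modal action in severe states is a high-dose cell;
#' its probability for the realized action is recorded on every step. The
#' hazard intercept is calibrated by bisection so the realized mortality
#' matches `target_mortality`.
#'
#' Per-step rewards are filled in under the configured reward specification
#' with the configured (default all-ones) weights.
#'
#' @param config a [cohort_config()].
#' @return A cohort step tibble: columns `subject_id`, `t` (hours, 0-based),
#'   `iv_bin`, `vp_bin`, flat `action` (0..24), `behavior_prob`, `reward`,
#'   the 30 feature columns, and patient-level `died`. Each patient's final
#'   row is the terminal state (NA action). The achieved mortality and
#'   calibrated intercept are attached as attributes.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    intercept <- config$hazard_intercept
    if (is.null(intercept)) {
      n_pilot <- min(config$n_patients, 2500L)
      pilot_seeds <- sample.int(.Machine$integer.max, 2)
      mort_at <- function(b) {
        mean(vapply(pilot_seeds, function(ps) {
          pilot <- with_seed(ps, run_cohort_sim(config, b, n_pilot))
          mean(tapply(pilot$died, pilot$subject_id, any))
        }, numeric(1)))
      }
      lo <- -22; hi <- 1
      for (i in 1:15) {
        mid <- (lo + hi) / 2
        if (mort_at(mid) < config$target_mortality) lo <- mid else hi <- mid
      }
      intercept <- (lo + hi) / 2
    }
    cohort <- run_cohort_sim(config, intercept)
    achieved <- mean(tapply(cohort$died, cohort$subject_id, any))
    if (abs(achieved - config$target_mortality) > 0.02) {
      warning(sprintf(
        "achieved mortality %.3f differs from target %.3f by more than 2 percentage points",
        achieved, config$target_mortality
      ))
    }
    cohort <- reward_trajectory(
      config$behavior_reward_spec,
      if (is.null(config$behavior_reward_weights)) {
        config$reward_label_weights
      } else {
        config$behavior_reward_weights
      },
      cohort
    )
    attr(cohort, "achieved_mortality") <- achieved
    attr(cohort, "hazard_intercept") <- intercept
    attr(cohort, "config") <- config
    cohort
  })
}

#' Resample irregular observations onto an hourly grid
#'
#' Linear interpolation between observations and constant extrapolation at
#' the edges, per feature; the output grid has no missing values.
#'
#' @param irregular_series long tibble with columns `time_h`, `feature`,
#'   `value`; at least one observation per feature.
#' @param interval grid spacing in hours (default 1).
#' @return Wide tibble with `time_h` and one column per feature.
#' @export
resample_to_grid <- function(irregular_series, interval = 1) {
  if (!nrow(irregular_series)) stop("empty observation series")
  stopifnot(all(c("time_h", "feature", "value") %in% names(irregular_series)))
  grid <- seq(
    floor(min(irregular_series$time_h)),
    ceiling(max(irregular_series$time_h)),
    by = interval
  )
  irregular_series |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 1) {
        return(tibble::tibble(time_h = grid, value = df$value))
      }
      out <- stats::approx(df$time_h, df$value, xout = grid, rule = 2)
      tibble::tibble(time_h = out$x, value = out$y)
    }) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value") |>
    dplyr::arrange(.data$time_h)
}

#' Write / read a cohort with its features sidecar
#'
#' The step table is written as CSV in the package trajectory record format
#' (plus the feature columns); the sidecar lists the 30 feature names and
#' units.
#'
#' @param cohort a cohort step tibble.
#' @param steps_path,features_path output file paths.
#' @return `read_cohort()` returns the step tibble.
#' @export
write_cohort <- function(cohort, steps_path,
                         features_path = sub("\\.csv$", "_features.csv", steps_path)) {
  readr::write_csv(cohort, steps_path)
  readr::write_csv(sepsis_feature_table(), features_path)
  invisible(steps_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(steps_path) {
  readr::read_csv(steps_path, show_col_types = FALSE, progress = FALSE)
}
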