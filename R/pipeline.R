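#' End-to-end experiment configuration
#'
#' Bundles the per-stage configurations of a full study: cohort simulation,
#' policy learning per reward specification, off-policy evaluation, and
#' mortality calibration. The global seed is propagated to every stage
#' (stage seeds are fixed offsets of it).
#'
#' @param cohort a [cohort_config()].
#' @param dirl a [dirl_config()] used as the template for every reward spec.
#' @param reward_specs character vector of [reward_spec()] names to compare.
#' @param cluster_k clusters for the calibration stage.
#' @param n_buckets mortality-curve buckets.
#' @param ope_discount discount used by the evaluation stage.
#' @param bootstrap_reps bootstrap resamples for mortality intervals.
#' @param seed global seed.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(cohort,
                              dirl = dirl_config(),
                              reward_specs = reward_spec_names(),
                              cluster_k = 300, n_buckets = 20,
                              ope_discount = 0.99, bootstrap_reps = 1000,
                              seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(dirl, "dirl_config"))
  structure(
    list(
      cohort = cohort, dirl = dirl, reward_specs = reward_specs,
      cluster_k = as.integer(cluster_k), n_buckets = as.integer(n_buckets),
      ope_discount = ope_discount, bootstrap_reps = as.integer(bootstrap_reps),
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

# Convert a cohort into the tabular trajectory format over clustered states:
# state = cluster id, action = flat action + 1. Terminal rows become the
# next_state of the preceding step.
cohort_to_tabular <- function(cohort, cluster_model) {
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$t)
  cl <- assign_clusters(cluster_model, cohort)
  step <- !is.na(cohort$action)
  i_step <- which(step)
  tibble::tibble(
    subject_id = cohort$subject_id[i_step],
    t = cohort$t[i_step],
    state = cl[i_step],
    action = as.integer(cohort$action[i_step]) + 1L,
    reward = cohort$reward[i_step],
    next_state = cl[i_step + 1L],
    behavior_prob = cohort$behavior_prob[i_step],
    died = cohort$died[i_step]
  )
}

# greedy one-hot policy of a dirl fit over cluster centers (raw feature space)
policy_on_clusters <- function(fit, cluster_model, n_actions = 25) {
  centers_raw <- sweep(
    sweep(cluster_model$centers, 2, cluster_model$scale, "*"),
    2, cluster_model$center, "+"
  )
  colnames(centers_raw) <- sepsis_features()
  acts <- greedy_actions(fit, centers_raw) + 1L
  deterministic_policy(acts, n_actions)
}

# behavior policy probabilities aggregated per cluster (empirical frequencies)
behavior_policy_on_clusters <- function(tab, k, n_actions = 25) {
  cnt <- matrix(0, k, n_actions)
  tt <- table(factor(tab$state, levels = seq_len(k)),
    factor(tab$action, levels = seq_len(n_actions))
  )
  cnt[] <- as.numeric(tt)
  cnt <- cnt + 1e-3 # smoothing keeps the support condition satisfiable
  policy_table(cnt / rowSums(cnt))
}

#' Compare learned policies across reward specifications
#'
#' Trains one policy per reward specification on the training split,
#' evaluates each (and the clinician behavior policy) with doubly robust and
#' dueling-weight estimators on the clustered held-out set, and maps the
#' estimated returns to mortality through the calibrated
#' mortality-versus-return curve.
#'
#' @param config an [experiment_config()].
#' @param cohort optionally a pre-simulated cohort matching
#'   `config$cohort`; simulated when `NULL`.
#' @return A tibble with one row per reward spec plus the clinician row:
#'   columns `policy`, `v_dr`, `v_dw`, `mortality`, `lower`, `upper`. The
#'   curve, fits and intermediate artifacts are attached as attributes.
#' @export
run_reward_spec_comparison <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$cohort)
  sp <- split_dataset(cohort, 0.8, seed = config$seed + 1L)
  cm <- cluster_states(sp$train,
    k = config$cluster_k,
    seed = config$seed + 2L
  )
  qtab <- sarsa_q(sp$train, cm,
    discount = config$ope_discount,
    seed = config$seed + 3L
  )
  curve <- build_mortality_curve(sp$test, cm, qtab, config$n_buckets)
  tab_test <- cohort_to_tabular(sp$test, cm)
  pi_b <- behavior_policy_on_clusters(tab_test, cm$k)
  model_b <- value_model(qtab, pi_b)
  rows <- list()
  fits <- list()
  for (sname in config$reward_specs) {
    dcfg <- config$dirl
    dcfg$reward_spec <- reward_spec(sname)
    dcfg$seed <- config$seed + 10L
    fit <- train_dirl(sp$train, dcfg)
    fits[[sname]] <- fit
    pi_e <- policy_on_clusters(fit, cm)
    model_e <- value_model(qtab, pi_e)
    v_dr <- estimate_dr(tab_test, pi_e, pi_b,
      model = model_e,
      discount = config$ope_discount
    )$estimate
    v_dw <- estimate_dw(tab_test, pi_e, pi_b,
      model = model_e,
      discount = config$ope_discount
    )$estimate
    mort <- estimate_policy_mortality(curve, v_dr,
      bootstrap_reps = config$bootstrap_reps, seed = config$seed + 4L
    )
    rows[[sname]] <- tibble::tibble(
      policy = sname, v_dr = v_dr, v_dw = v_dw,
      mortality = mort$mortality, lower = mort$lower, upper = mort$upper
    )
  }
  v_dr_b <- estimate_dr(tab_test, pi_b, pi_b,
    model = model_b,
    discount = config$ope_discount
  )$estimate
  v_dw_b <- estimate_dw(tab_test, pi_b, pi_b,
    model = model_b,
    discount = config$ope_discount
  )$estimate
  mort_b <- estimate_policy_mortality(curve, v_dr_b,
    bootstrap_reps = config$bootstrap_reps, seed = config$seed + 4L
  )
  rows[["clinician"]] <- tibble::tibble(
    policy = "clinician", v_dr = v_dr_b, v_dw = v_dw_b,
    mortality = mort_b$mortality, lower = mort_b$lower, upper = mort_b$upper
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "curve") <- curve
  attr(out, "fits") <- fits
  attr(out, "cluster_model") <- cm
  attr(out, "q_table") <- qtab
  attr(out, "cohort") <- cohort
  attr(out, "test") <- sp$test
  out
}

#' Action-map comparison of a learned policy against the clinician
#'
#' Counts every test-set state's greedy action of the learned policy and the
#' clinician's logged action on the 5 x 5 dose grid, and summarizes the
#' relative difference in mean dose bins.
#'
#' @param fit a [train_dirl()] fit (or `NULL` to compare the behavior policy
#'   with itself).
#' @param test cohort step tibble.
#' @return List with `policy_map`, `behavior_map` (5 x 5 count matrices),
#'   `modal_policy`, `modal_behavior` ((iv, vp) pairs), and
#'   `iv_dose_change`/`vp_dose_change` (relative change of the learned
#'   policy's mean dose bin versus the clinician's).
#' @export
run_policy_action_report <- function(fit, test) {
  steps <- test[!is.na(test$action), , drop = FALSE]
  behavior_map <- summarize_action_distribution(steps)
  if (is.null(fit)) {
    pol_actions <- steps$action
  } else {
    pol_actions <- greedy_actions(fit, steps)
  }
  policy_map <- summarize_action_distribution(tibble::tibble(action = pol_actions))
  modal <- function(m) {
    w <- which(m == max(m), arr.ind = TRUE)[1, ]
    c(iv = unname(w[1]) - 1L, vp = unname(w[2]) - 1L)
  }
  mean_dose <- function(a) c(iv = mean(a %/% 5L), vp = mean(a %% 5L))
  db <- mean_dose(steps$action)
  dp <- mean_dose(pol_actions)
  list(
    policy_map = policy_map, behavior_map = behavior_map,
    modal_policy = modal(policy_map), modal_behavior = modal(behavior_map),
    iv_dose_change = unname((dp["iv"] - db["iv"]) / max(db["iv"], 1e-9)),
    vp_dose_change = unname((dp["vp"] - db["vp"]) / max(db["vp"], 1e-9))
  )
}

#' Run the full study pipeline
#'
#' simulate, discover mortality drivers, train one policy per reward spec,
#' evaluate off-policy, calibrate mortality, and archive every stage's
#' artifacts (delimited tables plus a JSON manifest of stage seeds) in a run
#' directory.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest (invisibly a list), with the comparison table at
#'   `$comparison`.
#' @export
run_full_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  pft <- build_patient_feature_table(cohort)
  report <- fit_minitree(pft$table, pft$labels, seed = config$seed + 5L)
  readr::write_csv(tidy(report), file.path(out_dir, "feature_importance.csv"))
  comparison <- run_reward_spec_comparison(config, cohort = cohort)
  readr::write_csv(comparison, file.path(out_dir, "reward_spec_comparison.csv"))
  curve <- attr(comparison, "curve")
  readr::write_csv(
    tibble::as_tibble(curve),
    file.path(out_dir, "mortality_curve.csv")
  )
  fits <- attr(comparison, "fits")
  cand <- comparison[comparison$policy != "clinician", ]
  best <- cand$policy[which.max(cand$v_dr)]
  act <- run_policy_action_report(fits[[best]], attr(comparison, "test"))
  utils::write.csv(act$policy_map, file.path(out_dir, "policy_action_map.csv"))
  utils::write.csv(act$behavior_map, file.path(out_dir, "behavior_action_map.csv"))
  manifest <- list(
    seed = config$seed,
    stages = list(
      simulate = config$cohort$seed,
      split = config$seed + 1L, cluster = config$seed + 2L,
      sarsa = config$seed + 3L, bootstrap = config$seed + 4L,
      minitree = config$seed + 5L, dirl = config$seed + 10L
    ),
    n_patients = config$cohort$n_patients,
    achieved_mortality = attr(cohort, "achieved_mortality"),
    mortality_drivers = report$top_k,
    best_policy = best,
    dose_change = list(iv = act$iv_dose_change, vp = act$vp_dose_change)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest$comparison <- comparison
  invisible(manifest)
}
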