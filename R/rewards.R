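#' Clinically guided reward specifications
#'
#' The package scores one treatment step by weighted, squashed changes in six
#' severity indicators between consecutive hourly states:
#' \deqn{reward = \sum_{i \in I} W_i \tanh(S_i)}
#' where the indicator deltas are
#' `s0` = QSOFA_t - QSOFA_{t+1}, `s1` = SOFA_t - SOFA_{t+1}
#' (score decreases are improvements),
#' `s2` = MAP_{t+1} - MAP_t, `s3` = Lactate_{t+1} - Lactate_t,
#' `s4` = PaO2_{t+1} - PaO2_t, `s5` = PT_{t+1} - PT_t
#' (raw increases; the learned weights carry the clinical sign).
#' The seven named specifications select index subsets:
#' consensus severity scores (`sepsis3.0`: \{0,1\}), septic-shock indicators
#' (`sepsis3.0plus`: \{2,3\}), the two mortality-critical features discovered
#' by the tree stage (`sepsis4.0`: \{4,5\}), and their pairwise/total sums.
#'
#' @param name one of `"sepsis3.0"`, `"sepsis3.0plus"`, `"sepsis4.0"`,
#'   `"sepsis3.0_3.0plus"`, `"sepsis3.0_4.0"`, `"sepsis3.0plus_4.0"`,
#'   `"sepsis_all"`.
#' @return A `reward_spec` object with fields `name` and `index_set`
#'   (0-based indicator indices).
#' @export
reward_spec <- function(name = c(
                          "sepsis3.0", "sepsis3.0plus", "sepsis4.0",
                          "sepsis3.0_3.0plus", "sepsis3.0_4.0",
                          "sepsis3.0plus_4.0", "sepsis_all"
                        )) {
  name <- match.arg(name)
  index_set <- switch(name,
    "sepsis3.0" = 0:1,
    "sepsis3.0plus" = 2:3,
    "sepsis4.0" = 4:5,
    "sepsis3.0_3.0plus" = 0:3,
    "sepsis3.0_4.0" = c(0:1, 4:5),
    "sepsis3.0plus_4.0" = 2:5,
    "sepsis_all" = 0:5
  )
  structure(list(name = name, index_set = as.integer(index_set)),
    class = "reward_spec"
  )
}

#' @rdname reward_spec
#' @export
reward_spec_names <- function() {
  c(
    "sepsis3.0", "sepsis3.0plus", "sepsis4.0",
    "sepsis3.0_3.0plus", "sepsis3.0_4.0", "sepsis3.0plus_4.0", "sepsis_all"
  )
}

#' @export
print.reward_spec <- function(x, ...) {
  cat(sprintf(
    "<reward_spec> %s: indicators {%s}\n", x$name,
    paste(x$index_set, collapse = ", ")
  ))
  invisible(x)
}

#' Indicator weight vector
#'
#' The six learnable weights \eqn{W_0, \ldots, W_5} of the reward family.
#' No sign constraint is imposed: the inverse-RL stage is responsible for
#' learning whether an indicator's increase is beneficial or adverse.
#'
#' @param w numeric vector of length 6 (default all 1, the pre-learning
#'   initialization).
#' @return A named numeric vector classed `reward_weights`.
#' @export
reward_weights <- function(w = rep(1, 6)) {
  w <- as.numeric(w)
  if (length(w) != 6 || any(!is.finite(w))) {
    stop("`w` must be 6 finite numbers")
  }
  names(w) <- paste0("w", 0:5)
  class(w) <- "reward_weights"
  w
}

#' The six indicator feature names
#'
#' Column names, in indicator order 0..5, that states must carry for reward
#' computation: QSOFA, SOFA, mean arterial pressure, lactate, PaO2 and
#' prothrombin time.
#' @return Character vector of length 6.
#' @export
indicator_features <- function() {
  c(
    "qsofa_score", "sofa_score", "map_mmHg",
    "lactate_mmol_per_L", "pao2_mmHg", "pt_seconds"
  )
}

#' Indicator deltas between consecutive states
#'
#' Computes the six signed indicator changes feeding the reward family. The
#' severity scores enter as decreases (`s0`, `s1`) and the physiologic
#' measurements as increases (`s2`..`s5`); see [reward_spec()].
#'
#' @param state_t,state_t1 named numeric vectors, single-row data frames, or
#'   aligned multi-row data frames carrying the six indicator columns of
#'   [indicator_features()].
#' @return A tibble with columns `s0`..`s5` (one row per state pair).
#' @export
indicator_deltas <- function(state_t, state_t1) {
  grab <- function(x, nm) {
    if (is.data.frame(x)) {
      if (!nm %in% names(x)) stop("state lacks indicator feature `", nm, "`")
      x[[nm]]
    } else {
      if (!nm %in% names(x)) stop("state lacks indicator feature `", nm, "`")
      unname(x[[nm]])
    }
  }
  feats <- indicator_features()
  tibble::tibble(
    s0 = grab(state_t, feats[1]) - grab(state_t1, feats[1]),
    s1 = grab(state_t, feats[2]) - grab(state_t1, feats[2]),
    s2 = grab(state_t1, feats[3]) - grab(state_t, feats[3]),
    s3 = grab(state_t1, feats[4]) - grab(state_t, feats[4]),
    s4 = grab(state_t1, feats[5]) - grab(state_t, feats[5]),
    s5 = grab(state_t1, feats[6]) - grab(state_t, feats[6])
  )
}

#' Evaluate a reward specification
#'
#' \eqn{\sum_{i \in I} w_i \tanh(s_i)} over the spec's indicator subset;
#' bounded in absolute value by \eqn{\sum_{i \in I} |w_i|}.
#'
#' @param spec a [reward_spec()].
#' @param weights a [reward_weights()] vector.
#' @param deltas a tibble of indicator deltas (columns `s0`..`s5`), as from
#'   [indicator_deltas()].
#' @return Numeric vector, one reward per delta row.
#' @export
compute_reward <- function(spec, weights, deltas) {
  stopifnot(inherits(spec, "reward_spec"))
  w <- as.numeric(weights)
  cols <- paste0("s", spec$index_set)
  miss <- setdiff(cols, names(deltas))
  if (length(miss)) stop("deltas lack columns: ", paste(miss, collapse = ", "))
  out <- numeric(nrow(deltas))
  for (i in spec$index_set) {
    out <- out + w[i + 1] * tanh(deltas[[paste0("s", i)]])
  }
  out
}

#' Relabel a cohort's rewards under a reward specification
#'
#' Recomputes the per-step reward of every trajectory from its own indicator
#' changes, leaving all other columns untouched. Terminal rows (no action)
#' keep an `NA` reward.
#'
#' @param spec a [reward_spec()].
#' @param weights a [reward_weights()] vector.
#' @param cohort a cohort step tibble (one row per patient-hour carrying the
#'   indicator features; see [simulate_cohort()]).
#' @param terminal_reward optional outcome bonus magnitude (default 0, i.e.
#'   intermediate indicator rewards only): each patient's final treatment
#'   step additionally receives `-terminal_reward` if the patient died and
#'   `+terminal_reward` otherwise. Intended for ablation studies.
#' @return The cohort with its `reward` column replaced.
#' @export
reward_trajectory <- function(spec, weights, cohort, terminal_reward = 0) {
  feats <- indicator_features()
  miss <- setdiff(feats, names(cohort))
  if (length(miss)) stop("cohort lacks indicator features: ", paste(miss, collapse = ", "))
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$t)
  d <- stepwise_deltas(cohort)
  r <- compute_reward(spec, weights, d)
  r[is.na(d$s0)] <- NA_real_
  if (terminal_reward != 0) {
    n <- nrow(cohort)
    step <- !is.na(r)
    # last non-terminal step of each patient carries the outcome bonus
    is_last_step <- step &
      !c(step[-1] & cohort$subject_id[-1] == cohort$subject_id[-n], FALSE)
    sgn <- ifelse(cohort$died[is_last_step], -1, 1)
    r[is_last_step] <- r[is_last_step] + sgn * terminal_reward
  }
  cohort$reward <- r
  cohort
}

# vectorized within-patient one-step indicator deltas; NA on each patient's
# final (terminal) row. Assumes rows sorted by subject_id, t.
stepwise_deltas <- function(cohort) {
  feats <- indicator_features()
  cur <- as.matrix(cohort[, feats])
  n <- nrow(cur)
  nxt <- rbind(cur[-1, , drop = FALSE], NA_real_)
  last_row <- c(cohort$subject_id[-1] != cohort$subject_id[-n], TRUE)
  nxt[last_row, ] <- NA_real_
  tibble::tibble(
    s0 = cur[, 1] - nxt[, 1], s1 = cur[, 2] - nxt[, 2],
    s2 = nxt[, 3] - cur[, 3], s3 = nxt[, 4] - cur[, 4],
    s4 = nxt[, 5] - cur[, 5], s5 = nxt[, 6] - cur[, 6]
  )
}

#' Per-step tanh indicator features of a cohort
#'
#' Returns `tanh` of the six indicator deltas for every non-terminal step —
#' the sufficient statistics through which rewards depend linearly on the
#' weight vector (used by the inverse-RL weight updates).
#'
#' @inheritParams reward_trajectory
#' @return The non-terminal steps of `cohort` with added columns `f0`..`f5`
#'   (\eqn{\tanh S_i}).
#' @export
tanh_delta_features <- function(cohort) {
  feats <- indicator_features()
  out <- dplyr::arrange(cohort, .data$subject_id, .data$t)
  d <- stepwise_deltas(out)
  for (i in 0:5) out[[paste0("f", i)]] <- tanh(d[[paste0("s", i)]])
  out[!is.na(out$action), , drop = FALSE]
}
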