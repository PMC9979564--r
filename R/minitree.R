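#' Per-patient feature summaries with mortality labels
#'
#' Aggregates each patient's stay into one row of per-feature summaries
#' (mean, last and worst value over the stay; "worst" is the adverse
#' direction of [feature_hazard_table()], falling back to the maximum for
#' direction-free features) with the patient's terminal mortality label.
#' Per-patient aggregation avoids within-patient pseudo-replication of the
#' mortality label across correlated hourly rows.
#'
#' @param trajectories cohort step tibble (see [simulate_cohort()]).
#' @return List with `table` (tibble, one row per patient) and `labels`
#'   (logical vector of deaths).
#' @export
build_patient_feature_table <- function(trajectories) {
  if (!nrow(trajectories)) stop("empty cohort")
  feats <- intersect(sepsis_features(), names(trajectories))
  if (!length(feats)) stop("cohort carries no known features")
  ht <- feature_hazard_table()
  dir <- stats::setNames(ht$direction, ht$feature)
  agg <- trajectories |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      died = any(.data$died),
      dplyr::across(dplyr::all_of(feats),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          last = ~ dplyr::last(.x)
        ),
        .names = "{.col}__{.fn}"
      ),
      .groups = "drop"
    )
  worst <- trajectories |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(feats), function(x) {
        d <- dir[dplyr::cur_column()]
        if (is.na(d) || d >= 0) max(x, na.rm = TRUE) else min(x, na.rm = TRUE)
      }, .names = "{.col}__worst"),
      .groups = "drop"
    )
  tab <- dplyr::left_join(agg, worst, by = "subject_id")
  list(
    table = dplyr::select(tab, -"died"),
    labels = tab$died
  )
}

#' Fit the mini-tree mortality-driver model
#'
#' A depth-limited tree ensemble (default: 100 trees of depth at most 3) fit
#' to the binary mortality label over per-patient feature summaries, scoring
#' features by normalized impurity-decrease importance. Importances of the
#' mean/last/worst summaries of one feature are pooled to a single
#' per-feature score. A single-CART variant is selectable with
#' `method = "single_tree"`.
#'
#' @param table per-patient feature tibble from [build_patient_feature_table()]
#'   (the `subject_id` column is ignored).
#' @param labels logical or 0/1 mortality labels.
#' @param num_trees,max_depth ensemble size and depth cap.
#' @param method `"ensemble"` (ranger) or `"single_tree"` (rpart).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @return A `feature_importance_report`: list with `importances` (named,
#'   normalized to sum 1), `ranking`, `top_k` (two highest), `method`, and
#'   `aggregation` notes.
#' @export
fit_minitree <- function(table, labels, num_trees = 100, max_depth = 3,
                         method = c("ensemble", "single_tree"), seed = 1) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("mortality labels contain a single class; cannot rank features")
  }
  x <- dplyr::select(table, -dplyr::any_of("subject_id"))
  x <- x[vapply(x, is.numeric, logical(1))]
  if (method == "ensemble") {
    fit <- ranger::ranger(
      x = as.data.frame(x), y = factor(labels),
      num.trees = num_trees, max.depth = max_depth,
      importance = "impurity", seed = seed,
      num.threads = 1, probability = FALSE
    )
    imp <- fit$variable.importance
  } else {
    if (!requireNamespace("rpart", quietly = TRUE)) {
      stop("the single-tree variant requires the rpart package")
    }
    df <- as.data.frame(x)
    df$.label <- factor(labels)
    fit <- rpart::rpart(.label ~ ., df,
      method = "class",
      control = rpart::rpart.control(maxdepth = max_depth, cp = 0)
    )
    imp <- fit$variable.importance
    missing <- setdiff(names(x), names(imp))
    imp <- c(imp, stats::setNames(rep(0, length(missing)), missing))
  }
  imp[imp < 0] <- 0
  # pool the mean/last/worst summaries back to base features
  base <- sub("__(mean|last|worst)$", "", names(imp))
  pooled <- tapply(imp, base, sum)
  if (sum(pooled) == 0) pooled[] <- 1 / length(pooled)
  pooled <- pooled / sum(pooled)
  ord <- order(-pooled, names(pooled)) # ties broken lexicographically
  ranking <- names(pooled)[ord]
  structure(
    list(
      importances = stats::setNames(as.numeric(pooled)[ord], ranking),
      ranking = ranking,
      top_k = ranking[seq_len(min(2, length(ranking)))],
      method = method,
      aggregation = "per-patient mean/last/worst summaries, pooled per feature"
    ),
    class = "feature_importance_report"
  )
}

#' @export
print.feature_importance_report <- function(x, ...) {
  cat("<feature_importance_report>", x$method, "\n")
  top <- utils::head(x$importances, 5)
  for (i in seq_along(top)) {
    cat(sprintf("  %d. %s  %.3f\n", i, names(top)[i], top[i]))
  }
  invisible(x)
}

#' @export
tidy.feature_importance_report <- function(x, ...) {
  tibble::tibble(
    feature = names(x$importances),
    importance = as.numeric(x$importances),
    rank = seq_along(x$importances)
  )
}

#' @export
autoplot.feature_importance_report <- function(object, top_n = 10, ...) {
  df <- utils::head(tidy.feature_importance_report(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "normalized importance", y = NULL,
      title = "Mortality-critical features"
    )
}

#' Select the indicators wired into the discovered-driver reward
#'
#' Returns the top-k features of an importance report; with the default
#' `k = 2` these are the two features the discovered-driver reward term
#' tracks.
#'
#' @param report a [fit_minitree()] report.
#' @param k number of features.
#' @return Character vector of feature names.
#' @export
select_reward4_indicators <- function(report, k = 2) {
  stopifnot(inherits(report, "feature_importance_report"))
  if (k > length(report$ranking)) {
    stop("k exceeds the number of ranked features")
  }
  report$ranking[seq_len(k)]
}
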