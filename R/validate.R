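# Holdout segregation and classifier validation --------------------------

#' Segregate a subject-grouped, class-proportional holdout
#'
#' Subjects (never individual samples) are sampled class-proportionally into
#' the holdout, so all samples of a chosen subject leave the training
#' partition together and the holdout stays untouched by feature selection
#' and tuning.
#'
#' @param ds A [lipid_dataset].
#' @param labeling A `class_labeling` on `ds`.
#' @param fraction Holdout fraction of subjects per class profile.
#' @param seed Integer seed.
#' @return A list with `train` and `holdout` [lipid_dataset]s (restricted
#'   to the labeled samples) and `holdout_subjects`.
#' @export
split_holdout <- function(ds, labeling, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop_lipidmoe("holdout fraction must be in (0, 1)", "lipidmoe_split_error")
  }
  profile <- labeling |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(profile = paste(sort(unique(as.character(.data$label))),
                                     collapse = "+"),
                     .groups = "drop")
  small <- profile |> dplyr::count(.data$profile) |> dplyr::filter(.data$n < 5L)
  if (nrow(small)) {
    stop_lipidmoe(sprintf("class profile '%s' has fewer than 5 subjects",
                          small$profile[1L]), "lipidmoe_split_error")
  }
  holdout_subjects <- withr::with_seed(seed, {
    unlist(lapply(split(profile$subject_id, profile$profile), function(s) {
      sample(s, max(1L, round(fraction * length(s))))
    }), use.names = FALSE)
  })
  in_hold <- labeling$subject_id %in% holdout_subjects
  subset_ds <- function(ids) {
    out <- ds
    out$values <- ds$values[ids, , drop = FALSE]
    out$samples <- ds$samples[match(ids, ds$samples$sample_id), ]
    out
  }
  list(train = subset_ds(labeling$sample_id[!in_hold]),
       holdout = subset_ds(labeling$sample_id[in_hold]),
       holdout_subjects = holdout_subjects)
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls; 0.5 is chance for binary tasks
#' irrespective of class imbalance.
#'
#' @param y_true,y_pred Factors (or coercible) of equal length; `y_true`
#'   must contain both classes.
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.factor(y_true)
  y_pred <- factor(y_pred, levels = levels(y_true))
  stopifnot(length(y_true) == length(y_pred))
  present <- levels(y_true)[levels(y_true) %in% y_true]
  if (length(present) < 2L) {
    stop_lipidmoe("y_true must contain both classes", "lipidmoe_metric_error")
  }
  recalls <- vapply(present, function(lev) {
    idx <- y_true == lev
    mean(y_pred[idx] == lev)
  }, numeric(1))
  mean(recalls)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive sample
#' outscores a random negative one, ties counted one half.
#'
#' @param y_true Two-level factor (second level = positive class).
#' @param scores Continuous classifier scores, larger = more positive.
#' @return A number in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.factor(y_true)
  stopifnot(length(y_true) == length(scores))
  if (nlevels(droplevels(y_true)) < 2L) {
    stop_lipidmoe("y_true must contain both classes", "lipidmoe_metric_error")
  }
  pos <- y_true == levels(y_true)[2L]
  r <- rank(scores)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Validate feature sets on the untouched holdout
#'
#' 100 runs (5 splits x 20 repeats by default): per run a class-proportional
#' 80% subject subset of the training partition is drawn, each tuned family
#' is fitted on the feature-set columns, and the fit is evaluated on a
#' random 80% sample subset of the holdout with balanced accuracy and
#' ROC-AUC. With `permute = TRUE` the training labels are shuffled before
#' fitting — the overfitting control: informative features still only reach
#' chance performance. Medians with nonparametric 95% CIs (2.5th/97.5th
#' percentiles) are reported per family; a family is flagged as separated
#' from chance when its CI excludes 0.5.
#'
#' @param train,holdout [lipid_dataset]s from [split_holdout()] (already
#'   standardized with training statistics).
#' @param labeling_task `"timepoint"` or `"neuropathy"`.
#' @param feature_set Character vector of features to train on.
#' @param families Classifier families.
#' @param tuned Tuned specs from [tune_classifiers()] (defaults per family
#'   if missing).
#' @param n_splits,n_repeats Run geometry (`n_splits * n_repeats` runs).
#' @param train_fraction Subject fraction of train drawn per run.
#' @param holdout_fraction Sample fraction of holdout drawn per run.
#' @param seed Integer seed.
#' @param permute Shuffle training labels per run (overfitting control).
#' @return A `validation_report`: list with `runs` (tibble run x family) and
#'   `summary` (per family and metric: median, ci_low, ci_high,
#'   separated_from_chance), plus the call geometry.
#' @export
validate <- function(train, holdout, labeling_task = "timepoint",
                     feature_set, families = c("svm", "rf", "logreg"),
                     tuned = NULL, n_splits = 5L, n_repeats = 20L,
                     train_fraction = 0.8, holdout_fraction = 0.8,
                     seed = 1L, permute = FALSE) {
  if (!length(feature_set)) {
    stop_lipidmoe("empty feature set", "lipidmoe_contract_error")
  }
  missing_f <- setdiff(feature_set,
                       intersect(colnames(train$values), colnames(holdout$values)))
  if (length(missing_f)) {
    stop_lipidmoe(paste0("features absent from a partition: ",
                         paste(missing_f, collapse = ", ")),
                  "lipidmoe_schema_error")
  }
  if (is.null(tuned)) {
    tuned <- lapply(setNames(families, families), default_classifier_spec,
                    task = labeling_task)
  }
  lab_tr <- make_labeling(train, labeling_task)
  lab_ho <- make_labeling(holdout, labeling_task)
  xy_tr <- labeling_xy(train, lab_tr, feature_set)
  xy_ho <- labeling_xy(holdout, lab_ho, feature_set)
  profile <- lab_tr |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(profile = paste(sort(unique(as.character(.data$label))),
                                     collapse = "+"),
                     .groups = "drop")
  n_runs <- n_splits * n_repeats
  rows <- list()
  withr::with_seed(derive_seed(seed, "validate"), {
    for (run in seq_len(n_runs)) {
      # subject-grouped 80% of train, class-proportional over profiles
      subj <- unlist(lapply(split(profile$subject_id, profile$profile),
                            function(s) sample(s, max(1L, round(train_fraction *
                                                                  length(s))))),
                     use.names = FALSE)
      tr_idx <- which(xy_tr$subject %in% subj)
      ho_idx <- sort(sample(seq_along(xy_ho$y),
                            max(2L, round(holdout_fraction * length(xy_ho$y)))))
      y_tr <- xy_tr$y[tr_idx]
      if (permute) y_tr <- sample(y_tr)
      y_ho <- xy_ho$y[ho_idx]
      if (nlevels(droplevels(y_ho)) < 2L || nlevels(droplevels(y_tr)) < 2L) next
      for (fam in families) {
        model <- tryCatch(
          fit_classifier(tuned[[fam]], xy_tr$x[tr_idx, , drop = FALSE],
                         droplevels(y_tr),
                         seed = derive_seed(seed, sprintf("v%d%s", run, fam))),
          error = function(e) NULL)
        if (is.null(model)) next
        sc <- score_classifier(model, xy_ho$x[ho_idx, , drop = FALSE])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          run = run, family = fam,
          balanced_accuracy = balanced_accuracy(
            y_ho, predict_class(model, xy_ho$x[ho_idx, , drop = FALSE])),
          roc_auc = roc_auc(y_ho, sc))
      }
    }
  })
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    tidyr::pivot_longer(c("balanced_accuracy", "roc_auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$family, .data$metric) |>
    dplyr::summarise(median = median(.data$value),
                     ci_low = unname(quantile(.data$value, 0.025)),
                     ci_high = unname(quantile(.data$value, 0.975)),
                     .groups = "drop") |>
    dplyr::mutate(separated_from_chance = .data$ci_low > 0.5 | .data$ci_high < 0.5)
  structure(list(runs = runs, summary = summary, permuted = permute,
                 feature_set = feature_set, task = labeling_task,
                 n_runs = n_runs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> task '%s', %d features, %d runs%s\n",
              x$task, length(x$feature_set), x$n_runs,
              if (x$permuted) " (permuted training labels)" else ""))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) x$summary

#' @export
glance.validation_report <- function(x, ...) {
  ba <- dplyr::filter(x$summary, .data$metric == "balanced_accuracy")
  tibble::tibble(task = x$task, n_features = length(x$feature_set),
                 n_runs = x$n_runs, permuted = x$permuted,
                 median_balanced_accuracy = median(ba$median),
                 all_separated_from_chance = all(ba$separated_from_chance))
}

#' Plot validation medians with percentile intervals
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot of per-family medians and 95% percentile CIs with the
#'   chance line at 0.5.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$family, y = .data$median,
                               ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("Holdout validation (%s features%s)",
                                  length(object$feature_set),
                                  if (object$permuted) ", permuted" else "")) +
    ggplot2::theme_minimal()
}

#' Freeze one classifier per family on the full training partition
#'
#' @param train Standardized training [lipid_dataset].
#' @param labeling_task Task name.
#' @param feature_set Features to train on.
#' @param families Classifier families.
#' @param tuned Tuned specs (defaults if missing).
#' @param seed Integer seed.
#' @return Named list of fitted models.
#' @export
fit_frozen <- function(train, labeling_task = "timepoint", feature_set,
                       families = c("svm", "rf", "logreg"), tuned = NULL,
                       seed = 1L) {
  if (is.null(tuned)) {
    tuned <- lapply(setNames(families, families), default_classifier_spec,
                    task = labeling_task)
  }
  lab <- make_labeling(train, labeling_task)
  xy <- labeling_xy(train, lab, feature_set)
  lapply(setNames(families, families), function(fam) {
    fit_classifier(tuned[[fam]], xy$x, xy$y,
                   seed = derive_seed(seed, paste0("frozen", fam)))
  })
}

#' Apply frozen classifiers to an external cohort
#'
#' No refitting: the models trained on the analysis cohort are applied to
#' repeated random 80% sample subsets of the external cohort, giving
#' percentile confidence intervals for the transferred performance.
#'
#' @param models Named list from [fit_frozen()].
#' @param external_ds External, preprocessed and standardized
#'   [lipid_dataset].
#' @param labeling_task Task name.
#' @param feature_set Features the models expect; all must be present.
#' @param n_splits,n_repeats Run geometry.
#' @param subset_fraction Sample fraction per run.
#' @param seed Integer seed.
#' @return A `validation_report`.
#' @export
external_apply <- function(models, external_ds, labeling_task = "timepoint",
                           feature_set, n_splits = 5L, n_repeats = 20L,
                           subset_fraction = 0.8, seed = 1L) {
  missing_f <- setdiff(feature_set, colnames(external_ds$values))
  if (length(missing_f)) {
    stop_lipidmoe(paste0("external cohort lacks features: ",
                         paste(missing_f, collapse = ", ")),
                  "lipidmoe_schema_error")
  }
  lab <- make_labeling(external_ds, labeling_task)
  xy <- labeling_xy(external_ds, lab, feature_set)
  n_runs <- n_splits * n_repeats
  rows <- list()
  withr::with_seed(derive_seed(seed, "external"), {
    for (run in seq_len(n_runs)) {
      idx <- sort(sample(seq_along(xy$y),
                         max(2L, round(subset_fraction * length(xy$y)))))
      y <- xy$y[idx]
      if (nlevels(droplevels(y)) < 2L) next
      for (fam in names(models)) {
        sc <- score_classifier(models[[fam]], xy$x[idx, , drop = FALSE])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          run = run, family = fam,
          balanced_accuracy = balanced_accuracy(
            y, predict_class(models[[fam]], xy$x[idx, , drop = FALSE])),
          roc_auc = roc_auc(y, sc))
      }
    }
  })
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    tidyr::pivot_longer(c("balanced_accuracy", "roc_auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$family, .data$metric) |>
    dplyr::summarise(median = median(.data$value),
                     ci_low = unname(quantile(.data$value, 0.025)),
                     ci_high = unname(quantile(.data$value, 0.975)),
                     .groups = "drop") |>
    dplyr::mutate(separated_from_chance = .data$ci_low > 0.5 | .data$ci_high < 0.5)
  structure(list(runs = runs, summary = summary, permuted = FALSE,
                 feature_set = feature_set, task = labeling_task,
                 n_runs = n_runs),
            class = "validation_report")
}
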