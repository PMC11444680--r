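# Classifier family wrappers --------------------------------------------
# Uniform fit/score interface over e1071 (SVM), ranger (random forest) and
# glmnet (penalized logistic regression). The second factor level is the
# positive class throughout; scores are oriented so larger = more positive.

default_classifier_spec <- function(family,
                                    task = c("timepoint", "neuropathy")) {
  task <- match.arg(task)
  switch(family,
    svm = list(family = "svm", kernel = "sigmoid", cost = 1,
               penalty = "L1", tuned = FALSE),
    rf = list(family = "rf",
              num_trees = if (task == "timepoint") 1200L else 200L,
              max_depth = 10L, tuned = FALSE),
    logreg = list(family = "logreg", penalty = "L2", lambda = 0.05,
                  tuned = FALSE),
    stop_lipidmoe(sprintf("unknown classifier family '%s'", family),
                  "lipidmoe_parameter_error"))
}

fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(nlevels(y) == 2L)
  switch(spec$family,
    svm = {
      fit <- e1071::svm(x, y, kernel = spec$kernel %||% "sigmoid",
                        cost = spec$cost %||% 1, scale = FALSE,
                        probability = FALSE)
      list(spec = spec, fit = fit, levels = levels(y))
    },
    rf = {
      xx <- x; colnames(xx) <- make_safe_names(colnames(x))
      fit <- ranger::ranger(
        x = xx, y = y, probability = TRUE,
        num.trees = spec$num_trees %||% 500L,
        max.depth = if (is.null(spec$max_depth) || spec$max_depth == 0L) NULL
                    else spec$max_depth,
        seed = seed, num.threads = 1L)
      list(spec = spec, fit = fit, levels = levels(y))
    },
    logreg = {
      alpha <- if (identical(spec$penalty, "L1")) 1 else 0
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                            lambda = spec$lambda %||% 0.05,
                            standardize = FALSE)
      list(spec = spec, fit = fit, levels = levels(y))
    })
}

make_safe_names <- function(x) paste0("f", seq_along(x))

# continuous score per family: SVM decision margin, forest positive-class
# vote fraction, logistic modeled probability
score_classifier <- function(model, x) {
  pos <- model$levels[2L]
  switch(model$spec$family,
    svm = {
      dv <- attr(predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      s <- dv[, 1L]
      # e1071 orients the margin towards the first class seen in training
      if (grepl(paste0("^", pos, "/"), colnames(dv)[1L])) s else -s
    },
    rf = {
      xx <- x; colnames(xx) <- make_safe_names(colnames(x))
      predict(model$fit, xx, num.threads = 1L)$predictions[, pos]
    },
    logreg = {
      drop(predict(model$fit, x, type = "response"))
    })
}

predict_class <- function(model, x) {
  s <- score_classifier(model, x)
  thr <- if (model$spec$family == "svm") 0 else 0.5
  factor(ifelse(s > thr, model$levels[2L], model$levels[1L]),
         levels = model$levels)
}

# linear-model importance used by SFM/RFE: |w| for linear SVM,
# impurity importance for forests, |beta| for penalized logistic regression
selection_importance <- function(family, x, y, tuned, seed = 1L) {
  switch(family,
    svm = {
      fit <- e1071::svm(x, y, kernel = "linear",
                        cost = tuned$svm$cost %||% 1, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      abs(w)[colnames(x)]
    },
    rf = {
      fit <- ranger::ranger(x = x, y = y, num.trees = 100L,
                            importance = "impurity", seed = seed,
                            num.threads = 1L)
      imp <- fit$variable.importance[colnames(x)]
      pmax(imp, 0)
    },
    logreg = {
      alpha <- if (identical(tuned$logreg$penalty, "L1")) 1 else 0
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                            lambda = tuned$logreg$lambda %||% 0.05,
                            standardize = FALSE)
      imp <- abs(as.vector(fit$beta))
      names(imp) <- rownames(fit$beta)
      imp[colnames(x)]
    })
}

#' Tune classifier hyperparameters by cross-validated grid search
#'
#' Five-fold subject-grouped grid search per family, scored by mean balanced
#' accuracy: SVM over kernel (linear, sigmoid) x cost, random forest over
#' trees (200, 600, 1200) x depth (5, 10, unlimited), logistic regression
#' over penalty (LASSO, Ridge) x lambda. Also tunes the `k` of the
#' F-statistic k-best / RFE selectors over the grid 1..18 per family, scored
#' by inner-CV balanced accuracy of the paired model on the top-k features.
#'
#' @param ds A standardized [lipid_dataset] (training partition only).
#' @param labeling A `class_labeling`.
#' @param families Character subset of `c("svm", "rf", "logreg")`.
#' @param k_grid Candidate k values for k-best/RFE.
#' @param n_folds Inner folds.
#' @param seed Integer seed.
#' @return A named list of tuned specs (one per family, `tuned = TRUE`,
#'   including the chosen `k`), with the grid-search table as attribute
#'   `"grid"`.
#' @export
tune_classifiers <- function(ds, labeling, families = c("svm", "rf", "logreg"),
                             k_grid = 1:18, n_folds = 5L, seed = 1L) {
  task <- labeling_task(labeling)
  xy <- labeling_xy(ds, labeling)
  folds <- grouped_stratified_folds(labeling, n_folds, 1L,
                                    derive_seed(seed, "tune"))[[1L]]
  grids <- list(
    svm = tidyr::expand_grid(kernel = c("linear", "sigmoid"),
                             cost = c(0.1, 1, 10)),
    rf = tidyr::expand_grid(num_trees = c(200L, 600L, 1200L),
                            max_depth = c(5L, 10L, 0L)),
    logreg = tidyr::expand_grid(penalty = c("L1", "L2"),
                                lambda = c(0.01, 0.05, 0.2)))
  grid_scores <- list()
  tuned <- list()
  for (fam in families) {
    grid <- grids[[fam]]
    scores <- vapply(seq_len(nrow(grid)), function(i) {
      spec <- c(list(family = fam), as.list(grid[i, ]))
      cv_balanced_accuracy(spec, xy, folds, seed)
    }, numeric(1))
    best <- which.max(scores)
    spec <- modifyList(default_classifier_spec(fam, task),
                       as.list(grid[best, ]))
    spec$family <- fam
    spec$tuned <- TRUE
    tuned[[fam]] <- spec
    grid_scores[[fam]] <- dplyr::mutate(grid, family = fam,
                                        balanced_accuracy = scores)
  }
  # k for the k-best / RFE selectors, per family
  f_stat <- univariate_f_statistics(xy$x, xy$y)
  ranked <- names(sort(-f_stat))
  for (fam in families) {
    k_scores <- vapply(k_grid, function(k) {
      feats <- ranked[seq_len(min(k, length(ranked)))]
      xy_k <- list(x = xy$x[, feats, drop = FALSE], y = xy$y,
                   subject = xy$subject)
      cv_balanced_accuracy(tuned[[fam]], xy_k, folds, seed)
    }, numeric(1))
    tuned[[fam]]$k <- k_grid[which.max(k_scores)]
  }
  attr(tuned, "grid") <- dplyr::bind_rows(grid_scores)
  tuned
}

cv_balanced_accuracy <- function(spec, xy, folds, seed) {
  bas <- vapply(seq_along(folds), function(f) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(xy$y), test_idx)
    y_tr <- droplevels(xy$y[train_idx])
    if (nlevels(y_tr) < 2L || length(unique(xy$y[test_idx])) < 2L) {
      return(NA_real_)
    }
    model <- tryCatch(
      fit_classifier(spec, xy$x[train_idx, , drop = FALSE], y_tr,
                     seed = derive_seed(seed, sprintf("cvfit%d", f))),
      error = function(e) NULL)
    if (is.null(model)) return(NA_real_)
    balanced_accuracy(xy$y[test_idx],
                      predict_class(model, xy$x[test_idx, , drop = FALSE]))
  }, numeric(1))
  mean(bas, na.rm = TRUE)
}
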