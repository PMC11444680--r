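# Individual feature-selection experts -----------------------------------

#' Absolute Cohen's d effect sizes per feature
#'
#' `|d| = |mean1 - mean2| / pooled SD`, with the two-sample pooled-variance
#' formula. Features with zero pooled SD score 0.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Two-level factor.
#' @return Named numeric vector of `|d|` scores.
#' @export
cohens_d_scores <- function(x, y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) {
    stop_lipidmoe("Cohen's d needs exactly two classes", "lipidmoe_task_error")
  }
  i1 <- y == levels(y)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2L || n2 < 2L) {
    stop_lipidmoe("both classes need at least 2 samples", "lipidmoe_task_error")
  }
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2L, var)
  v2 <- apply(x[!i1, , drop = FALSE], 2L, var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- abs(m1 - m2) / sp
  d[!is.finite(d)] <- 0
  d
}

# one-way F statistic per feature (2 groups); constant features get F = 0
univariate_f_statistics <- function(x, y) {
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  n <- length(y)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(y)) {
    idx <- y == lev
    mu <- colMeans(x[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (mu - grand)^2
    ssw <- ssw + colSums(sweep(x[idx, , drop = FALSE], 2L, mu, `-`)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[!is.finite(f)] <- 0
  f
}

#' Univariate F-statistic feature selection
#'
#' One-way F statistic per feature with three selection modes:
#' `fpr` keeps features with `p < alpha` (per-test false-positive rate),
#' `fwe` keeps `p < alpha / d` (Bonferroni family-wise control), and
#' `kbest` keeps the top `k` by F (ties to the smaller feature index).
#'
#' @param x Numeric matrix (samples x features).
#' @param y Two-level factor.
#' @param mode `"fpr"`, `"fwe"` or `"kbest"`.
#' @param alpha Significance level for `fpr`/`fwe`.
#' @param k Number of features for `kbest`.
#' @return Character vector of selected feature names.
#' @export
univariate_f_selection <- function(x, y, mode = c("fpr", "fwe", "kbest"),
                                   alpha = 0.05, k = NULL) {
  mode <- match.arg(mode)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) {
    stop_lipidmoe("F selection needs exactly two classes", "lipidmoe_task_error")
  }
  f <- univariate_f_statistics(x, y)
  n <- length(y); d <- ncol(x)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  p[f == 0] <- 1
  switch(mode,
    fpr = colnames(x)[p < alpha],
    fwe = colnames(x)[p < alpha / d],
    kbest = {
      if (is.null(k)) stop_lipidmoe("kbest needs k", "lipidmoe_parameter_error")
      if (k > d) stop_lipidmoe("k exceeds feature count", "lipidmoe_parameter_error")
      colnames(x)[order(-f, seq_along(f))[seq_len(k)]]
    })
}

# SelectFromModel: keep features whose model importance is at least the
# mean importance
sfm_selection <- function(family, x, y, tuned, seed = 1L) {
  imp <- selection_importance(family, x, y, tuned, seed)
  colnames(x)[imp >= mean(imp)]
}

# Recursive feature elimination down to k features. Each step refits the
# model and drops the least important `max(1, floor(rfe_step * remaining))`
# features; set rfe_step = 0 to eliminate exactly one feature per step.
rfe_selection <- function(family, x, y, tuned, k, seed = 1L, rfe_step = 0.1) {
  feats <- colnames(x)
  step_i <- 0L
  while (length(feats) > k) {
    imp <- selection_importance(family, x[, feats, drop = FALSE], y, tuned,
                                derive_seed(seed, sprintf("rfe%d", step_i)))
    n_drop <- max(1L, floor(rfe_step * length(feats)))
    n_drop <- min(n_drop, length(feats) - k)
    drop <- names(sort(imp, decreasing = FALSE))[seq_len(n_drop)]
    if (!length(drop) || !any(drop %in% feats)) {
      stop_lipidmoe("RFE importance lost feature names", "lipidmoe_contract_error")
    }
    feats <- setdiff(feats, drop)
    step_i <- step_i + 1L
  }
  feats
}

#' The default 13-expert selection ensemble
#'
#' PCA variable importance, Cohen's d, F-based FPR and FWE control, and the
#' k-best, SelectFromModel and RFE mechanisms each instantiated for the
#' linear SVM, random forest and logistic regression — 13 selectors in
#' total.
#'
#' @param alpha Significance level for the FPR/FWE selectors.
#' @return A tibble with columns `id`, `kind`, `model`, `alpha`.
#' @export
default_ensemble <- function(alpha = 0.05) {
  models <- c("svm", "rf", "logreg")
  dplyr::bind_rows(
    tibble::tibble(id = "pca_importance", kind = "pca_importance",
                   model = NA_character_, alpha = NA_real_),
    tibble::tibble(id = "cohens_d", kind = "cohens_d",
                   model = NA_character_, alpha = NA_real_),
    tibble::tibble(id = "fpr", kind = "fpr", model = NA_character_,
                   alpha = alpha),
    tibble::tibble(id = "fwe", kind = "fwe", model = NA_character_,
                   alpha = alpha),
    tibble::tibble(id = paste0("kbest_", models), kind = "kbest",
                   model = models, alpha = NA_real_),
    tibble::tibble(id = paste0("sfm_", models), kind = "sfm",
                   model = models, alpha = NA_real_),
    tibble::tibble(id = paste0("rfe_", models), kind = "rfe",
                   model = models, alpha = NA_real_))
}

#' Run one selector on one training fold
#'
#' Dispatches a selector specification (one row of [default_ensemble()]) on
#' a training fold and returns the features its rule selects. A model-fit
#' failure yields a zero-length selection (recorded upstream), never an
#' error.
#'
#' @param selector One-row tibble (columns `id`, `kind`, `model`, `alpha`).
#' @param x Training matrix (samples x features, standardized).
#' @param y Two-level factor.
#' @param tuned Tuned specs from [tune_classifiers()] (provides `k`,
#'   penalties, costs).
#' @param seed Integer seed for the stochastic selectors.
#' @param rfe_step RFE elimination fraction (see `rfe_selection`).
#' @return Character vector of selected feature names.
#' @export
selector_round <- function(selector, x, y, tuned, seed = 1L, rfe_step = 0.1) {
  kind <- selector$kind
  tryCatch(
    switch(kind,
      pca_importance = {
        ds <- quick_dataset(scale(x))
        pca_structure(ds)$important_features
      },
      cohens_d = abc_members(cabc_categorize(cohens_d_scores(x, y)), "A"),
      fpr = univariate_f_selection(x, y, "fpr", alpha = selector$alpha),
      fwe = univariate_f_selection(x, y, "fwe", alpha = selector$alpha),
      kbest = univariate_f_selection(x, y, "kbest",
                                     k = tuned[[selector$model]]$k),
      sfm = sfm_selection(selector$model, x, y, tuned, seed),
      rfe = rfe_selection(selector$model, x, y, tuned,
                          k = tuned[[selector$model]]$k, seed = seed,
                          rfe_step = rfe_step),
      stop_lipidmoe(sprintf("unknown selector kind '%s'", kind),
                    "lipidmoe_parameter_error")),
    lipidmoe_error = function(e) rlang::cnd_signal(e),
    error = function(e) character())
}

# minimal standardized dataset wrapper for fold-local PCA
quick_dataset <- function(x) {
  n <- nrow(x)
  samples <- tibble::tibble(sample_id = rownames(x) %||% paste0("s", seq_len(n)),
                            subject_id = paste0("s", seq_len(n)),
                            timepoint = "day1", neuropathy = "unknown")
  rownames(x) <- samples$sample_id
  ds <- lipid_dataset(x, samples)
  ds$standardized <- TRUE
  ds$log_transformed <- TRUE
  ds
}
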