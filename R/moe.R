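# Mixture-of-experts consensus feature selection -------------------------

# Subject-grouped, class-stratified repeated K-fold assignment.
# Subjects are stratified by their label profile (the sorted set of labels
# their samples carry — a paired subject contributes to both classes), then
# dealt round-robin into folds, so no subject ever straddles a fold border
# and fold class ratios stay close to the global ones.
# Returns a list of `n_repeats` lists of `n_splits` integer vectors of row
# indices into `labeling` (the held-out fold).
grouped_stratified_folds <- function(labeling, n_splits = 5L, n_repeats = 20L,
                                     seed = 1L) {
  profile <- labeling |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(profile = paste(sort(unique(as.character(.data$label))),
                                     collapse = "+"),
                     .groups = "drop")
  too_small <- profile |>
    dplyr::count(.data$profile) |>
    dplyr::filter(.data$n < n_splits)
  if (nrow(too_small)) {
    stop_lipidmoe(
      sprintf("class profile '%s' has fewer subjects (%d) than folds (%d)",
              too_small$profile[1L], too_small$n[1L], n_splits),
      "lipidmoe_fold_error")
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      fold_of <- integer(0)
      subj <- character(0)
      for (p in unique(profile$profile)) {
        members <- sample(profile$subject_id[profile$profile == p])
        fold_of <- c(fold_of, (seq_along(members) - 1L) %% n_splits + 1L)
        subj <- c(subj, members)
      }
      assign <- setNames(fold_of, subj)
      lapply(seq_len(n_splits), function(f) {
        unname(which(assign[labeling$subject_id] == f))
      })
    })
  })
}

#' Run the mixture-of-experts consensus feature selection
#'
#' Runs every selector of the ensemble on each training fold of a repeated
#' subject-grouped stratified cross-validation (default 5 splits x 20
#' repeats = 100 runs) and aggregates:
#'
#' 1. `counts`: how often each method selected each feature over the runs;
#' 2. per-method cABC on its counts — category A is the method's vote;
#' 3. `sum_score`: for each feature, the number of methods voting for it;
#' 4. `reduced_set`: cABC category A of the sum score;
#' 5. `sparse_set`: nested (depth-2) cABC category A of the sum score.
#'
#' Runs on the training partition only — the holdout must already have been
#' removed with [split_holdout()].
#'
#' @param ds A standardized [lipid_dataset] (training partition).
#' @param labeling A `class_labeling` on the training samples.
#' @param ensemble Selector tibble, see [default_ensemble()].
#' @param tuned Tuned specs from [tune_classifiers()]; computed here if
#'   missing.
#' @param n_splits,n_repeats Cross-validation geometry.
#' @param seed Integer seed; the tally is bit-reproducible given it.
#' @param rfe_step RFE elimination fraction per step.
#' @return A `selection_tally`: list with `counts` (method x feature
#'   matrix), `per_method_A`, `sum_score` (named vector), `reduced_set`,
#'   `sparse_set`, `n_runs`, `failures` (tibble of selector failures).
#' @export
run_moe <- function(ds, labeling, ensemble = default_ensemble(), tuned = NULL,
                    n_splits = 5L, n_repeats = 20L, seed = 1L,
                    rfe_step = 0.1) {
  if (is.null(tuned)) {
    tuned <- tune_classifiers(ds, labeling, seed = derive_seed(seed, "tune"))
  }
  xy <- labeling_xy(ds, labeling)
  folds <- grouped_stratified_folds(labeling, n_splits, n_repeats,
                                    derive_seed(seed, "folds"))
  feats <- colnames(xy$x)
  counts <- matrix(0L, nrow = nrow(ensemble), ncol = length(feats),
                   dimnames = list(ensemble$id, feats))
  failures <- list()
  run <- 0L
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(n_splits)) {
      run <- run + 1L
      train_idx <- setdiff(seq_along(xy$y), folds[[r]][[f]])
      x_tr <- xy$x[train_idx, , drop = FALSE]
      y_tr <- droplevels(xy$y[train_idx])
      for (m in seq_len(nrow(ensemble))) {
        sel <- selector_round(ensemble[m, ], x_tr, y_tr, tuned,
                              seed = derive_seed(seed, sprintf("run%d_m%d", run, m)),
                              rfe_step = rfe_step)
        if (!length(sel)) {
          failures[[length(failures) + 1L]] <-
            tibble::tibble(run = run, method = ensemble$id[m])
        }
        counts[m, sel] <- counts[m, sel] + 1L
      }
    }
  }
  per_method_A <- lapply(seq_len(nrow(ensemble)), function(m) {
    v <- counts[m, ]
    if (all(v == 0)) return(character())
    res <- suppressWarnings(cabc_categorize(v))
    if (res$degenerate) character() else abc_members(res, "A")
  })
  names(per_method_A) <- ensemble$id
  sum_score <- setNames(integer(length(feats)), feats)
  for (a in per_method_A) sum_score[a] <- sum_score[a] + 1L
  reduced_set <- abc_members(suppressWarnings(cabc_categorize(sum_score)), "A")
  sparse_set <- abc_members(suppressWarnings(nested_cabc(sum_score, depth = 2L)), "A")
  structure(
    list(counts = counts, per_method_A = per_method_A,
         sum_score = sum_score, reduced_set = reduced_set,
         sparse_set = sparse_set, n_runs = run,
         failures = dplyr::bind_rows(failures),
         task = labeling_task(labeling)),
    class = "selection_tally")
}

#' @export
print.selection_tally <- function(x, ...) {
  cat(sprintf("<selection_tally> task '%s': %d methods x %d features over %d runs\n",
              x$task, nrow(x$counts), ncol(x$counts), x$n_runs))
  cat(sprintf("  reduced set: %d features; sparse set: %d features\n",
              length(x$reduced_set), length(x$sparse_set)))
  if (nrow(x$failures)) {
    cat(sprintf("  %d selector failures recorded\n", nrow(x$failures)))
  }
  invisible(x)
}

#' @export
tidy.selection_tally <- function(x, ...) {
  tibble::tibble(
    feature = names(x$sum_score),
    sum_score = unname(x$sum_score),
    set = dplyr::case_when(
      names(x$sum_score) %in% x$sparse_set ~ "sparse",
      names(x$sum_score) %in% x$reduced_set ~ "reduced",
      TRUE ~ "not selected")) |>
    dplyr::arrange(dplyr::desc(.data$sum_score))
}

#' @export
glance.selection_tally <- function(x, ...) {
  tibble::tibble(n_methods = nrow(x$counts), n_features = ncol(x$counts),
                 n_runs = x$n_runs, n_reduced = length(x$reduced_set),
                 n_sparse = length(x$sparse_set),
                 n_failures = nrow(x$failures))
}

#' Plot the consensus sum score of a selection tally
#'
#' Bar plot of the per-feature selection sum score (0..number of methods),
#' colored by membership in the reduced and sparse sets.
#'
#' @param object A `selection_tally`.
#' @param top_n Show only the top-scoring features (default 60).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_tally <- function(object, top_n = 60L, ...) {
  df <- tidy(object) |> dplyr::slice_head(n = top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sum_score, y = .data$feature,
                                   fill = .data$set)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(sparse = "#54278f",
                                          reduced = "#9e9ac8",
                                          "not selected" = "grey80")) +
    ggplot2::labs(x = "methods selecting the lipid mediator (sum score)",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
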