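test_that("holdout split is subject-grouped, proportional and deterministic", {
  sim <- generate_lipidomics()
  ds <- apply_power(sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  sp <- split_holdout(ds, lab, fraction = 0.2, seed = 4L)
  # no subject straddles the partition border
  expect_length(intersect(sp$train$samples$subject_id,
                          sp$holdout$samples$subject_id), 0)
  # paired subjects keep both samples together
  expect_setequal(c(sp$train$samples$sample_id, sp$holdout$samples$sample_id),
                  lab$sample_id)
  sp2 <- split_holdout(ds, lab, fraction = 0.2, seed = 4L)
  expect_identical(sp$holdout_subjects, sp2$holdout_subjects)

  # 20 subjects per class profile at fraction 0.2 -> 4 subjects held out
  ids <- sprintf("s%02d", 1:40)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(ids, paste0("f", 1:3)))
  meta <- tibble::tibble(sample_id = ids, subject_id = ids,
                         timepoint = rep(c("day1", "day2"), each = 20),
                         neuropathy = rep(c("unknown", "no"), each = 20))
  ds2 <- lipid_dataset(x, meta)
  lab2 <- make_labeling(ds2, "timepoint")
  sp3 <- split_holdout(ds2, lab2, fraction = 0.2, seed = 1L)
  held <- table(ds2$samples$timepoint[ds2$samples$sample_id %in%
                                        sp3$holdout$samples$sample_id])
  expect_identical(unname(held[["day1"]]), 4L)
  expect_identical(unname(held[["day2"]]), 4L)

  expect_error(split_holdout(ds, lab, fraction = 0), class = "lipidmoe_split_error")
})

test_that("balanced accuracy and ROC-AUC follow their definitions", {
  y <- factor(c("n", "n", "n", "n", "p", "p", "p", "p"))
  expect_equal(balanced_accuracy(y, y), 1)
  # constant predictor -> 0.5
  expect_equal(balanced_accuracy(y, factor(rep("p", 8), levels = c("n", "p"))),
               0.5)
  # sensitivity 3/4, specificity 2/4 -> 0.625
  pred <- factor(c("p", "p", "n", "n", "p", "p", "p", "n"),
                 levels = c("n", "p"))
  expect_equal(balanced_accuracy(y, pred), 0.625)
  expect_error(balanced_accuracy(factor(rep("p", 3), levels = c("n", "p")),
                                 factor(rep("p", 3), levels = c("n", "p"))),
               class = "lipidmoe_metric_error")

  yy <- factor(c("pos", "neg", "pos", "neg"), levels = c("neg", "pos"))
  expect_equal(roc_auc(yy, c(0.9, 0.8, 0.3, 0.2)), 0.75) # 3 of 4 pairs
  expect_equal(roc_auc(yy, c(1, 1, 1, 1)), 0.5)           # all ties
  expect_equal(roc_auc(yy, c(0.9, 0.1, 0.8, 0.2)), 1)
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(10)
  sc <- rnorm(40); yl <- factor(rep(c("neg", "pos"), 20), levels = c("neg", "pos"))
  expect_equal(roc_auc(yl, sc),
               as.numeric(pROC::auc(pROC::roc(yl, sc, quiet = TRUE,
                                              direction = "<", levels = c("neg", "pos")))))
})

test_that("tuning returns the grid optimum and honors single-point grids", {
  sim <- generate_lipidomics(small_spec(seed = 19L))
  ds <- apply_power(sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  sp <- split_holdout(ds, lab, 0.2, seed = 3L)
  train <- z_standardize(sp$train)
  lab_tr <- make_labeling(train, "timepoint")
  tuned <- tune_classifiers(train, lab_tr, families = "logreg", seed = 5L)
  grid <- attr(tuned, "grid")
  best_row <- grid[which.max(grid$balanced_accuracy), ]
  expect_identical(tuned$logreg$penalty, best_row$penalty)
  expect_identical(tuned$logreg$lambda, best_row$lambda)
  expect_true(tuned$logreg$k %in% 1:18)
  expect_true(tuned$logreg$tuned)
})

test_that("validation separates a real signal and permutation destroys it", {
  sim <- generate_lipidomics(small_spec(seed = 23L, effect_size_time = 2.5))
  ds <- apply_power(sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  sp <- split_holdout(ds, lab, 0.2, seed = 6L)
  train <- z_standardize(sp$train)
  holdout <- scale_with_train(sp$holdout, train)

  fs <- sim$truth$time
  rep_real <- validate(train, holdout, "timepoint", fs, n_repeats = 5,
                       seed = 7L)
  ba <- dplyr::filter(rep_real$summary, metric == "balanced_accuracy")
  expect_true(all(ba$median > 0.7))
  expect_true(all(ba$ci_low <= ba$median & ba$median <= ba$ci_high))
  expect_true(all(rep_real$runs$balanced_accuracy >= 0 &
                    rep_real$runs$balanced_accuracy <= 1))

  rep_perm <- validate(train, holdout, "timepoint", fs, n_repeats = 5,
                       seed = 7L, permute = TRUE)
  bp <- dplyr::filter(rep_perm$summary, metric == "balanced_accuracy")
  expect_true(all(abs(bp$median - 0.5) <= 0.2))
  expect_true(all(bp$ci_low <= 0.5 & bp$ci_high >= 0.5))

  expect_error(validate(train, holdout, "timepoint", character()),
               class = "lipidmoe_contract_error")
  expect_error(validate(train, holdout, "timepoint", "no_such_feature"),
               class = "lipidmoe_schema_error")
})

test_that("pure-noise features never separate from chance", {
  sim <- generate_lipidomics(small_spec(seed = 29L))
  ds <- apply_power(sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  sp <- split_holdout(ds, lab, 0.2, seed = 8L)
  train <- z_standardize(sp$train)
  holdout <- scale_with_train(sp$holdout, train)
  rep_null <- validate(train, holdout, "timepoint", sim$truth$decoys,
                       n_repeats = 5, seed = 9L)
  ba <- dplyr::filter(rep_null$summary, metric == "balanced_accuracy")
  expect_false(any(ba$separated_from_chance))
})

test_that("frozen classifiers transfer to an external cohort without refitting", {
  spec <- small_spec(seed = 37L, effect_size_time = 2.5)
  sim <- generate_lipidomics(spec)
  ds <- apply_power(sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  sp <- split_holdout(ds, lab, 0.2, seed = 10L)
  train <- z_standardize(sp$train)
  holdout <- scale_with_train(sp$holdout, train)
  fs <- sim$truth$time
  models <- fit_frozen(train, "timepoint", fs, seed = 2L)

  # external cohort = the holdout itself -> report close to validate()'s
  ext_id <- external_apply(models, holdout, "timepoint", fs,
                           n_repeats = 5, seed = 3L)
  ba_id <- dplyr::filter(ext_id$summary, metric == "balanced_accuracy")
  expect_true(all(ba_id$median > 0.7))

  # attenuated second cohort: above chance but below the holdout value
  second <- generate_second_cohort(spec, sim$truth, attenuation = 0.3,
                                   n_subjects = 20L, n_drop_features = 4L)
  ext_ds <- apply_power(second$dataset, 0)
  ext_ds <- scale_with_train(ext_ds, train)
  ext <- external_apply(models, ext_ds, "timepoint", fs,
                        n_repeats = 5, seed = 4L)
  ba_ext <- dplyr::filter(ext$summary, metric == "balanced_accuracy")
  expect_lt(mean(ba_ext$median), mean(ba_id$median))
  expect_gt(mean(ba_ext$median), 0.5)

  expect_error(external_apply(models, ext_ds, "timepoint",
                              c(fs, "missing_feature")),
               class = "lipidmoe_schema_error")
})

test_that("a holdout-only leakage canary never enters the selected sets", {
  fx_sim <- generate_lipidomics(small_spec(seed = 41L))
  ds <- apply_power(fx_sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  sp <- split_holdout(ds, lab, 0.2, seed = 12L)
  # canary: equals the class label on holdout rows, pure noise on train
  canary <- rnorm(nrow(ds$values))
  names(canary) <- rownames(ds$values)
  hold_ids <- sp$holdout$samples$sample_id
  canary[hold_ids] <- ifelse(
    ds$samples$timepoint[match(hold_ids, ds$samples$sample_id)] == "day2",
    10, -10)
  ds$values <- cbind(ds$values, CANARY_001 = canary[rownames(ds$values)])
  ds$features <- dplyr::bind_rows(
    ds$features, tibble::tibble(feature_name = "CANARY_001",
                                feature_class = NA_character_))
  sp2 <- list(train = ds, holdout = NULL)
  train <- ds
  train$values <- ds$values[sp$train$samples$sample_id, ]
  train$samples <- sp$train$samples
  train <- z_standardize(train)
  lab_tr <- make_labeling(train, "timepoint")
  tuned <- tune_classifiers(train, lab_tr, seed = 3L)
  tally <- run_moe(train, lab_tr, tuned = tuned, n_splits = 5,
                   n_repeats = 2, seed = 13L)
  expect_false("CANARY_001" %in% tally$reduced_set)
  expect_false("CANARY_001" %in% tally$sparse_set)
})
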