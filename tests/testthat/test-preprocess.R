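test_that("omnibus normality statistic matches the reference values", {
  # expected values computed with an independent reference implementation
  # of the skewness/kurtosis omnibus test on these exact seeded draws
  set.seed(101); x <- rnorm(500)
  res <- dagostino_pearson(x)
  expect_equal(res$statistic, 1.2169708059, tolerance = 1e-8)
  expect_equal(res$p_value, 0.5441744502, tolerance = 1e-8)
  expect_gt(res$p_value, 0.05)

  set.seed(202); y <- rexp(500)
  res <- dagostino_pearson(y)
  expect_equal(res$statistic, 156.5556558137, tolerance = 1e-8)
  expect_lt(res$p_value, 0.001)

  set.seed(303); z <- runif(60)
  expect_equal(dagostino_pearson(z)$statistic, 17.8964772930,
               tolerance = 1e-8)

  expect_error(dagostino_pearson(rnorm(10)),
               class = "lipidmoe_sample_size_error")
})

test_that("Tukey-ladder scan picks log for log-normal and identity for Gaussian", {
  sim <- generate_lipidomics(small_spec(seed = 3L, n_subjects = 15L,
                                        n_day1_only = 0L, n_features = 12L,
                                        n_informative_time = 0L,
                                        n_informative_neuropathy = 0L))
  scan <- scan_tukey_ladder(sim$dataset)
  expect_identical(sort(unique(scan$per_power$power)),
                   c(-2, -1, -0.5, 0, 0.5, 1, 2))
  expect_identical(scan$chosen_power, 0)

  # positive-shifted Gaussian data: identity wins under the tie rule
  set.seed(8)
  g <- matrix(rnorm(40 * 10, mean = 50, sd = 2), 40, 10)
  ds <- matrix_dataset(g, standardized = FALSE)
  scan_g <- scan_tukey_ladder(ds)
  expect_identical(scan_g$chosen_power, 1)

  # nonpositive values break powers <= 0
  bad <- matrix_dataset(matrix(c(-1, rep(1, 19)), 5, 4), standardized = FALSE)
  expect_error(scan_tukey_ladder(bad), class = "lipidmoe_domain_error")
})

test_that("missingness filter drops features first, then samples, and is idempotent", {
  x <- matrix(1, 5, 5, dimnames = list(paste0("s", 1:5), paste0("f", 1:5)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:5),
                         subject_id = paste0("p", 1:5),
                         timepoint = "day1", neuropathy = "unknown")

  # one feature 40% missing, no bad samples -> only that feature dropped
  x1 <- x; x1[1:2, "f3"] <- NA
  flt <- filter_missing(lipid_dataset(x1, meta))
  expect_identical(dim(flt$dataset$values), c(5L, 4L))
  expect_identical(flt$report$dropped_features, "f3")
  expect_length(flt$report$dropped_samples, 0)

  # sample s1 is 40% missing overall but only because of feature f3's
  # column; after f3 is dropped its missingness over retained features is
  # 25% > 20% -> still dropped; s2 falls to 0% -> retained
  x2 <- x
  x2[1, c("f3", "f4")] <- NA   # s1: 2/5 missing, 1/4 after f3 dropped
  x2[2, "f3"] <- NA            # s2: 1/5 missing, 0/4 after
  x2[3:5, "f3"] <- NA          # makes f3 100% missing
  flt2 <- filter_missing(lipid_dataset(x2, meta))
  expect_identical(flt2$report$dropped_features, "f3")
  expect_identical(flt2$report$dropped_samples, "s1")
  expect_identical(dim(flt2$dataset$values), c(4L, 4L))

  # identity on complete data, idempotence in general
  flt3 <- filter_missing(lipid_dataset(x, meta))
  expect_identical(flt3$dataset$values, x)
  again <- filter_missing(flt2$dataset)
  expect_identical(again$dataset$values, flt2$dataset$values)
  expect_length(again$report$dropped_features, 0)

  allbad <- x; allbad[, ] <- NA
  expect_error(filter_missing(lipid_dataset(allbad, meta)),
               class = "lipidmoe_empty_dataset_error")
})

test_that("random-forest imputation beats medians on correlated data and is deterministic", {
  spec <- small_spec(seed = 17L, n_subjects = 30L, n_day1_only = 10L,
                     n_features = 20L, n_blocks = 2L, block_rho = 0.7,
                     missing_rate = 0)
  sim <- generate_lipidomics(spec)
  ds <- apply_power(sim$dataset, 0)
  truth_vals <- ds$values
  set.seed(99)
  mask <- matrix(runif(length(truth_vals)) < 0.1, nrow(truth_vals))
  ds$values[mask] <- NA

  imp <- rf_impute(ds, seed = 7L)
  expect_false(anyNA(imp$values))
  # observed cells untouched
  expect_identical(imp$values[!mask], truth_vals[!mask])

  rmse <- sqrt(mean((imp$values[mask] - truth_vals[mask])^2))
  med <- apply(ds$values, 2L, median, na.rm = TRUE)
  med_mat <- matrix(med, nrow(ds$values), ncol(ds$values), byrow = TRUE)
  rmse_med <- sqrt(mean((med_mat[mask] - truth_vals[mask])^2))
  expect_lte(rmse, rmse_med)

  imp2 <- rf_impute(ds, seed = 7L)
  expect_identical(imp$values, imp2$values)

  # complete data returned unchanged
  complete <- apply_power(generate_lipidomics(spec)$dataset, 0)
  expect_identical(rf_impute(complete, seed = 1L)$values, complete$values)
})

test_that("z-standardization is partition-aware and idempotent", {
  sim <- generate_lipidomics(small_spec(seed = 12L))
  ds <- apply_power(sim$dataset, 0)
  std <- z_standardize(ds)
  expect_equal(unname(colMeans(std$values)), rep(0, ncol(std$values)),
               tolerance = 1e-12)
  expect_equal(unname(apply(std$values, 2, sd)), rep(1, ncol(std$values)),
               tolerance = 1e-12)

  # fit on train only: holdout means generally differ from 0
  train_ids <- ds$samples$sample_id[1:20]
  hold_ids <- setdiff(ds$samples$sample_id, train_ids)
  std_tr <- z_standardize(ds, fit_on = train_ids)
  expect_gt(max(abs(colMeans(std_tr$values[hold_ids, ]))), 0.01)

  # idempotence with the same fitting partition
  twice <- z_standardize(std, fit_on = rownames(std$values))
  expect_equal(twice$values, std$values, tolerance = 1e-12)

  const <- ds; const$values[, 1] <- 5
  expect_error(z_standardize(const), class = "lipidmoe_constant_feature_error")
})
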