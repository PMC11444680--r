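# Preprocessing: transformation, missingness, imputation, scaling --------

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the omnibus
#' statistic `K2 = Z(skewness)^2 + Z(kurtosis)^2`, referred to a chi-square
#' distribution with 2 degrees of freedom. The skewness normalization follows
#' D'Agostino's transformation and the kurtosis normalization
#' Anscombe-Glynn's; both are undefined for very small samples, so at least
#' 20 observed values are required.
#'
#' @param x Numeric vector; `NA`s are removed.
#' @return A tibble with columns `statistic` (K2), `p_value`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) {
    stop_lipidmoe("D'Agostino-Pearson test needs at least 20 observed values",
                  "lipidmoe_sample_size_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) {
    stop_lipidmoe("constant input: normality test undefined",
                  "lipidmoe_constant_feature_error")
  }

  # skewness: D'Agostino (1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  g2 <- m4 / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  z_kurt <- ((1 - 2 / (9 * a)) - sign(denom) * abs((1 - 2 / a) / denom)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  tibble::tibble(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
                 n = n)
}

tukey_power <- function(x, lambda) {
  if (lambda == 0) log(x) else x^lambda
}

#' Scan Tukey's ladder of powers for the globally best transformation
#'
#' Applies each candidate power transform `x^lambda` (`lambda = 0` is the
#' natural log) to every feature and assesses per-feature normality with the
#' D'Agostino-Pearson omnibus test. The chosen power maximizes the number of
#' features compatible with normality (p > 0.05); ties go to the power
#' closest to 1 (no transformation).
#'
#' @param ds A [lipid_dataset] of strictly positive observed concentrations.
#' @param powers Candidate exponents.
#' @return A `transform_report`: list with `per_power` tibble (power,
#'   feature, statistic, p), `normal_counts` tibble and `chosen_power`.
#' @export
scan_tukey_ladder <- function(ds, powers = c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
  vals <- ds$values
  if (any(powers <= 0) && any(vals[!is.na(vals)] <= 0)) {
    bad <- colnames(vals)[colSums(vals <= 0, na.rm = TRUE) > 0][1L]
    stop_lipidmoe(
      sprintf("nonpositive value in feature '%s': powers <= 0 undefined", bad),
      "lipidmoe_domain_error")
  }
  per_power <- purrr::map_dfr(powers, function(lam) {
    purrr::map_dfr(colnames(vals), function(f) {
      res <- dagostino_pearson(tukey_power(vals[, f], lam))
      tibble::tibble(power = lam, feature = f,
                     statistic = res$statistic, p_value = res$p_value)
    })
  })
  counts <- per_power |>
    dplyr::group_by(.data$power) |>
    dplyr::summarise(n_normal = sum(.data$p_value > 0.05), .groups = "drop")
  best <- counts |>
    dplyr::filter(.data$n_normal == max(.data$n_normal)) |>
    dplyr::arrange(abs(.data$power - 1), .data$power)
  structure(list(per_power = per_power, normal_counts = counts,
                 chosen_power = best$power[1L]),
            class = "transform_report")
}

#' @export
print.transform_report <- function(x, ...) {
  cat("<transform_report> Tukey-ladder scan\n")
  print(x$normal_counts)
  cat(sprintf("chosen power: %g%s\n", x$chosen_power,
              if (x$chosen_power == 0) " (log)" else ""))
  invisible(x)
}

#' Apply a power transform to a dataset
#'
#' @param ds A [lipid_dataset].
#' @param power Exponent from Tukey's ladder; 0 applies the natural log and
#'   sets the dataset's `log_transformed` flag.
#' @return The transformed [lipid_dataset].
#' @export
apply_power <- function(ds, power = 0) {
  ds$values <- tukey_power(ds$values, power)
  ds$log_transformed <- power == 0
  ds
}

#' Filter out features and samples with excess missingness
#'
#' Features with a missing fraction strictly above `threshold` are dropped
#' first; samples are then assessed on the retained features only, so a
#' patient is never discarded because of a few globally bad analytes.
#' Boundary cases at exactly the threshold are retained.
#'
#' @param ds A [lipid_dataset].
#' @param threshold Maximum tolerated missing fraction, in `(0, 1)`.
#' @return A list with `dataset` (filtered) and `report` (a
#'   `preprocess_report` with `dropped_features`, `dropped_samples`).
#' @export
filter_missing <- function(ds, threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1)
  feat_frac <- colMeans(is.na(ds$values))
  drop_f <- colnames(ds$values)[feat_frac > threshold]
  keep_f <- setdiff(colnames(ds$values), drop_f)
  if (!length(keep_f)) {
    stop_lipidmoe("all features exceed the missingness threshold",
                  "lipidmoe_empty_dataset_error")
  }
  vals <- ds$values[, keep_f, drop = FALSE]
  samp_frac <- rowMeans(is.na(vals))
  drop_s <- rownames(vals)[samp_frac > threshold]
  keep_s <- setdiff(rownames(vals), drop_s)
  if (!length(keep_s)) {
    stop_lipidmoe("all samples exceed the missingness threshold",
                  "lipidmoe_empty_dataset_error")
  }
  out <- ds
  out$values <- vals[keep_s, , drop = FALSE]
  out$samples <- ds$samples[match(keep_s, ds$samples$sample_id), ]
  out$features <- ds$features[match(keep_f, ds$features$feature_name), ]
  report <- structure(list(dropped_features = drop_f, dropped_samples = drop_s,
                           threshold = threshold),
                      class = "preprocess_report")
  list(dataset = out, report = report)
}

#' Impute missing concentrations with iterative random forests
#'
#' Missing cells are initialized with feature medians, then each feature
#' with missingness is regressed on all other features with a random forest
#' and its missing cells overwritten with the forest's predictions. The
#' sweep is repeated until the normalized change of the imputed values falls
#' below `tol` or `max_iter` is reached. Observed cells are never altered;
#' the procedure is deterministic given `seed`.
#'
#' @param ds A [lipid_dataset], already filtered with [filter_missing()].
#' @param seed Integer seed.
#' @param max_iter Maximum number of sweeps.
#' @param tol Relative-change stopping tolerance.
#' @param num_trees Trees per forest.
#' @return The imputed [lipid_dataset] (no missing values).
#' @export
rf_impute <- function(ds, seed = 1L, max_iter = 10L, tol = 1e-3,
                      num_trees = 100L) {
  vals <- ds$values
  miss <- is.na(vals)
  if (!any(miss)) return(ds)
  if (any(colSums(!miss) < 2L)) {
    stop_lipidmoe("every feature needs at least 2 observed values",
                  "lipidmoe_imputation_error")
  }
  med <- apply(vals, 2L, median, na.rm = TRUE)
  for (j in seq_len(ncol(vals))) vals[miss[, j], j] <- med[j]

  # features ordered by increasing missingness, as iterative RF imputers do
  order_j <- order(colSums(miss))
  order_j <- order_j[colSums(miss)[order_j] > 0L]
  prev <- vals[miss]
  for (it in seq_len(max_iter)) {
    for (j in order_j) {
      obs <- !miss[, j]
      xx <- vals[, -j, drop = FALSE]
      colnames(xx) <- paste0("x", seq_len(ncol(xx)))
      fit <- ranger::ranger(
        x = xx[obs, , drop = FALSE], y = vals[obs, j],
        num.trees = num_trees, seed = derive_seed(seed, sprintf("imp_%d_%d", it, j)),
        num.threads = 1L)
      vals[!obs, j] <- predict(fit, xx[!obs, , drop = FALSE],
                               num.threads = 1L)$predictions
    }
    cur <- vals[miss]
    delta <- sum((cur - prev)^2) / max(sum(cur^2), .Machine$double.eps)
    prev <- cur
    if (delta < tol) break
  }
  ds$values <- vals
  ds
}

#' Z-standardize features using statistics from a fitting partition
#'
#' Per-feature means and SDs are estimated on `fit_on` rows only and applied
#' to the whole dataset, so holdout samples can be scaled with
#' training-partition statistics without information leakage.
#'
#' @param ds A log-transformed [lipid_dataset].
#' @param fit_on Sample ids to estimate the statistics on (default: all).
#' @return The standardized [lipid_dataset]; attributes
#'   `standardization_means`/`standardization_sds` record the statistics.
#' @export
z_standardize <- function(ds, fit_on = NULL) {
  fit_on <- fit_on %||% rownames(ds$values)
  stopifnot(length(fit_on) > 0, all(fit_on %in% rownames(ds$values)))
  fit <- ds$values[fit_on, , drop = FALSE]
  mu <- colMeans(fit, na.rm = TRUE)
  sds <- apply(fit, 2L, sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    bad <- colnames(fit)[!is.finite(sds) | sds == 0][1L]
    stop_lipidmoe(sprintf("constant feature on fitting partition: '%s'", bad),
                  "lipidmoe_constant_feature_error")
  }
  ds$values <- sweep(sweep(ds$values, 2L, mu, `-`), 2L, sds, `/`)
  ds$standardized <- TRUE
  attr(ds, "standardization_means") <- mu
  attr(ds, "standardization_sds") <- sds
  ds
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper chaining the ladder scan, the chosen power transform,
#' missingness filtering and random-forest imputation (standardization is
#' applied later, with statistics fitted on the training partition only).
#'
#' @param ds A raw [lipid_dataset] of positive concentrations.
#' @param threshold Missingness threshold for [filter_missing()].
#' @param seed Seed for the imputation forests.
#' @param powers Candidate Tukey powers.
#' @return A list with `dataset` (preprocessed), `transform_report` and
#'   `report` (missingness report).
#' @export
preprocess <- function(ds, threshold = 0.2, seed = 1L,
                       powers = c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
  flt <- filter_missing(ds, threshold)
  scan <- scan_tukey_ladder(flt$dataset, powers)
  out <- apply_power(flt$dataset, scan$chosen_power)
  out <- rf_impute(out, seed = seed)
  list(dataset = out, transform_report = scan, report = flt$report)
}
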