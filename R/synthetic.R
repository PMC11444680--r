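# Synthetic lipidomics generator ----------------------------------------

#' Specification of a synthetic lipidomics cohort
#'
#' The defaults emit the shape of the study cohort this package's pipeline
#' is designed for: 48 subjects (31 with a paired post-therapy sample, 17
#' with a baseline sample only) measured on 255 lipid mediators, i.e. a
#' 79 x 255 matrix with 48 day-1 and 31 day-2 samples, and 17 of the 31
#' day-2 subjects neuropathy-positive. Concentrations are log-normal:
#' a per-feature baseline abundance plus a correlated-block factor (lipid
#' classes co-regulate), a subject random effect shared between a subject's
#' two samples (pairing), and residual noise. Class effects are additive on
#' the log scale, expressed in units of the within-class log SD
#' `sqrt(subject_sd^2 + noise_sd^2)`. Missingness is injected MCAR after
#' exponentiation.
#'
#' @param n_subjects Total subjects; the first `n_subjects - n_day1_only`
#'   are paired (day-1 and day-2 samples).
#' @param n_day1_only Subjects lacking a day-2 sample.
#' @param n_features Number of lipid mediators.
#' @param n_informative_time Features shifted between day 1 and day 2.
#' @param n_informative_neuropathy Features additionally shifted in
#'   neuropathy-positive day-2 samples.
#' @param effect_size_time,effect_size_neuropathy Log-scale shifts in units
#'   of within-class SD.
#' @param subject_sd Between-subject random-effect SD (log scale).
#' @param noise_sd Residual SD (log scale).
#' @param base_log_mean_range Interval for the per-feature log abundance.
#' @param n_blocks Number of correlated feature blocks (lipid classes).
#' @param block_rho Within-block correlation of log concentrations.
#' @param missing_rate MCAR missingness probability in `[0, 1)`.
#' @param neuropathy_prevalence Fraction of paired subjects positive on day 2.
#' @param enriched_class_fraction Fraction of informative features drawn
#'   from the first annotated lipid class (sphingolipids), emulating
#'   class-level enrichment of the true signal.
#' @param n_decoys Number of declared decoy features (never informative), so
#'   selector specificity is measurable.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 48L,
                           n_day1_only = 17L,
                           n_features = 255L,
                           n_informative_time = 10L,
                           n_informative_neuropathy = 5L,
                           effect_size_time = 1.5,
                           effect_size_neuropathy = 1.0,
                           subject_sd = 0.3,
                           noise_sd = 0.5,
                           base_log_mean_range = c(0, 4),
                           n_blocks = 10L,
                           block_rho = 0.4,
                           missing_rate = 0.05,
                           neuropathy_prevalence = 17 / 31,
                           enriched_class_fraction = 0.4,
                           n_decoys = 10L,
                           seed = 13L) {
  spec <- list(
    n_subjects = as.integer(n_subjects), n_day1_only = as.integer(n_day1_only),
    n_features = as.integer(n_features),
    n_informative_time = as.integer(n_informative_time),
    n_informative_neuropathy = as.integer(n_informative_neuropathy),
    effect_size_time = effect_size_time,
    effect_size_neuropathy = effect_size_neuropathy,
    subject_sd = subject_sd, noise_sd = noise_sd,
    base_log_mean_range = base_log_mean_range,
    n_blocks = as.integer(n_blocks), block_rho = block_rho,
    missing_rate = missing_rate,
    neuropathy_prevalence = neuropathy_prevalence,
    enriched_class_fraction = enriched_class_fraction,
    n_decoys = as.integer(n_decoys),
    seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_day1_only > n_subjects)
      stop_lipidmoe("n_day1_only exceeds n_subjects", "lipidmoe_parameter_error")
    if (n_informative_time > n_features || n_informative_neuropathy > n_features)
      stop_lipidmoe("more informative features than features",
                    "lipidmoe_parameter_error")
    if (missing_rate < 0 || missing_rate >= 1)
      stop_lipidmoe("missing_rate must be in [0, 1)", "lipidmoe_parameter_error")
    if (block_rho < 0 || block_rho >= 1)
      stop_lipidmoe("block_rho must be in [0, 1)", "lipidmoe_parameter_error")
    if (effect_size_time < 0 || effect_size_neuropathy < 0)
      stop_lipidmoe("effect sizes must be >= 0", "lipidmoe_parameter_error")
    if (subject_sd < 0 || noise_sd <= 0)
      stop_lipidmoe("subject_sd must be >= 0 and noise_sd > 0",
                    "lipidmoe_parameter_error")
    if (neuropathy_prevalence < 0 || neuropathy_prevalence > 1)
      stop_lipidmoe("neuropathy_prevalence must be in [0, 1]",
                    "lipidmoe_parameter_error")
  })
  invisible(spec)
}

# canonical lipid-class labels used for the block annotation; the first
# class hosts the enriched fraction of informative features
lipid_class_names <- function(n_blocks) {
  base <- c("sphingolipid", "ceramide", "lysophospholipid", "eicosanoid",
            "endocannabinoid", "free_fatty_acid", "phospholipid",
            "triacylglycerol", "cholesteryl_ester", "oxylipin")
  if (n_blocks <= length(base)) base[seq_len(n_blocks)]
  else c(base, sprintf("lipid_class_%02d", seq_len(n_blocks - length(base))))
}

# block sizes: first block ~18% of features (sphingolipid share of the
# emulated panel), remainder split evenly
synthetic_blocks <- function(n_features, n_blocks) {
  if (n_blocks == 1L) return(rep(1L, n_features))
  first <- max(1L, round(0.18 * n_features))
  rest <- n_features - first
  sizes <- c(first, rep(rest %/% (n_blocks - 1L), n_blocks - 1L))
  extra <- n_features - sum(sizes)
  if (extra > 0) sizes[1L + seq_len(extra)] <- sizes[1L + seq_len(extra)] + 1L
  rep.int(seq_len(n_blocks), sizes)
}

#' Generate a synthetic lipidomics cohort with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `dataset` (a [lipid_dataset]) and `truth`
#'   (lists `time`, `neuropathy` of informative feature names, plus
#'   `decoys`, a disjoint set of declared null features).
#' @export
generate_lipidomics <- function(spec = synthetic_spec()) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, generate_core(spec))
}

generate_core <- function(spec, informative_time = NULL,
                          informative_neuropathy = NULL,
                          effect_multiplier = 1) {
  n_paired <- spec$n_subjects - spec$n_day1_only
  subjects <- sprintf("subj%03d", seq_len(spec$n_subjects))
  paired <- subjects[seq_len(n_paired)]

  samples <- dplyr::bind_rows(
    tibble::tibble(subject_id = subjects, timepoint = "day1"),
    tibble::tibble(subject_id = paired, timepoint = "day2"))
  samples$sample_id <- paste0(samples$subject_id, "_", samples$timepoint)

  # neuropathy outcome per paired subject, revealed only on day-2 rows
  n_pos <- round(spec$neuropathy_prevalence * n_paired)
  pos_subjects <- if (n_paired > 0) sample(paired, n_pos) else character()
  samples$neuropathy <- ifelse(
    samples$timepoint == "day2",
    ifelse(samples$subject_id %in% pos_subjects, "yes", "no"),
    "unknown")

  block <- synthetic_blocks(spec$n_features, spec$n_blocks)
  classes <- lipid_class_names(spec$n_blocks)
  abbrev <- toupper(substr(classes, 1L, 3L))
  feature_name <- sprintf("%s_%03d", abbrev[block],
                          as.integer(stats::ave(block, block, FUN = seq_along)))
  features <- tibble::tibble(feature_name = feature_name,
                             feature_class = classes[block])

  # informative features: a fraction from the first (enriched) class, the
  # rest spread over the remaining classes; decoys disjoint from both
  if (is.null(informative_time)) {
    in_class <- which(block == 1L)
    out_class <- which(block != 1L)
    n_enr <- min(length(in_class),
                 round(spec$enriched_class_fraction * spec$n_informative_time))
    informative_time <- feature_name[c(
      sample(in_class, n_enr),
      sample(out_class, spec$n_informative_time - n_enr))]
    pool <- setdiff(feature_name, informative_time)
    informative_neuropathy <- sample(pool, spec$n_informative_neuropathy)
  }
  decoy_pool <- setdiff(features$feature_name,
                        c(informative_time, informative_neuropathy))
  decoys <- sample(decoy_pool, min(spec$n_decoys, length(decoy_pool)))

  # the numeric field draws from its own derived seed, so a cohort with
  # supplied informative sets (external cohort) reproduces the same field
  # as one that sampled them
  withr::local_seed(derive_seed(spec$seed, "field"))
  n <- nrow(samples)
  d <- spec$n_features
  sigma <- sqrt(spec$subject_sd^2 + spec$noise_sd^2)
  subj_idx <- match(samples$subject_id, subjects)

  # latent z: sqrt(rho) * block factor + sqrt(1 - rho) * feature-private
  # part; both decompose into a subject effect (shared across a subject's
  # two samples) and sample-level noise, so var(z) = sigma^2 and the
  # within-block correlation is exactly block_rho
  draw_field <- function(k) {
    subj_part <- matrix(rnorm(spec$n_subjects * k, sd = spec$subject_sd),
                        spec$n_subjects, k)
    subj_part[subj_idx, , drop = FALSE] +
      matrix(rnorm(n * k, sd = spec$noise_sd), n, k)
  }
  w <- draw_field(spec$n_blocks)   # block-level latent
  v <- draw_field(d)               # feature-private latent
  z <- sqrt(spec$block_rho) * w[, block, drop = FALSE] +
    sqrt(1 - spec$block_rho) * v

  base <- runif(d, spec$base_log_mean_range[1L], spec$base_log_mean_range[2L])
  logx <- sweep(z, 2L, base, `+`)

  day2 <- samples$timepoint == "day2"
  shift_t <- effect_multiplier * spec$effect_size_time * sigma
  shift_n <- effect_multiplier * spec$effect_size_neuropathy * sigma
  it <- match(informative_time, feature_name)
  logx[day2, it] <- logx[day2, it, drop = FALSE] + shift_t
  pos <- day2 & samples$neuropathy == "yes"
  inp <- match(informative_neuropathy, feature_name)
  logx[pos, inp] <- logx[pos, inp, drop = FALSE] + shift_n

  values <- exp(logx)
  if (spec$missing_rate > 0) {
    values[runif(n * d) < spec$missing_rate] <- NA_real_
  }
  dimnames(values) <- list(samples$sample_id, feature_name)

  list(
    dataset = lipid_dataset(values, samples[, c("sample_id", "subject_id",
                                                "timepoint", "neuropathy")],
                            features),
    truth = list(time = informative_time,
                 neuropathy = informative_neuropathy,
                 decoys = decoys))
}

#' Generate an external validation cohort sharing the primary ground truth
#'
#' Emulates an independent second cohort: fewer subjects (all paired by
#' default, 26 subjects = 52 samples), a slightly shrunken lipid panel
#' (16 features dropped by default, 255 -> 239), and an attenuated effect
#' size, reproducing the weaker signal expected when frozen classifiers are
#' transferred to an external cohort.
#'
#' @param spec A [synthetic_spec()] describing the primary cohort; the
#'   second cohort reuses its distributional parameters.
#' @param truth Ground truth returned by [generate_lipidomics()] on `spec`.
#' @param attenuation Multiplier in `(0, 1]` applied to both effect sizes.
#' @param n_subjects,n_day1_only Cohort size (default 26 paired subjects).
#' @param n_drop_features Features removed from the panel; dropped from the
#'   non-informative, non-decoy pool so the shared truth stays measurable.
#' @param seed Seed for the second cohort (default derived from `spec$seed`).
#' @return A list with `dataset` (the external [lipid_dataset]) and `truth`.
#' @export
generate_second_cohort <- function(spec, truth, attenuation = 0.4,
                                   n_subjects = 26L, n_day1_only = 0L,
                                   n_drop_features = 16L,
                                   seed = derive_seed(spec$seed, "second_cohort")) {
  if (attenuation <= 0 || attenuation > 1) {
    stop_lipidmoe("attenuation must be in (0, 1]", "lipidmoe_parameter_error")
  }
  spec2 <- spec
  spec2$n_subjects <- as.integer(n_subjects)
  spec2$n_day1_only <- as.integer(n_day1_only)
  spec2$seed <- as.integer(seed)
  validate_synthetic_spec(spec2)
  res <- withr::with_seed(spec2$seed, {
    out <- generate_core(spec2, informative_time = truth$time,
                         informative_neuropathy = truth$neuropathy,
                         effect_multiplier = attenuation)
    keep_pool <- setdiff(out$dataset$features$feature_name,
                         c(truth$time, truth$neuropathy, truth$decoys))
    drop <- sample(keep_pool, min(n_drop_features, length(keep_pool)))
    out$drop <- drop
    out
  })
  ds <- res$dataset
  keep <- setdiff(colnames(ds$values), res$drop)
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$features <- ds$features[match(keep, ds$features$feature_name), ]
  list(dataset = ds, truth = res$truth)
}
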