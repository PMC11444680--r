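# End-to-end pipeline orchestration --------------------------------------

#' Build a pipeline configuration
#'
#' One configuration object drives the whole workflow: simulate (or read) ->
#' preprocess -> unsupervised structure -> holdout split -> tune -> consensus
#' feature selection -> validation (real and permuted) -> group statistics.
#' Every stochastic stage derives its seed deterministically from the
#' master seed. The configuration round-trips losslessly through YAML.
#'
#' @param spec A [synthetic_spec()] (used when no input paths are given).
#' @param values_path,metadata_path,annotation_path Optional input tables
#'   read with [read_lipid_dataset()] instead of simulating.
#' @param tasks Tasks to analyze.
#' @param holdout_fraction Subject fraction reserved for validation.
#' @param missing_threshold Missingness filter threshold.
#' @param n_splits,n_repeats Cross-validation geometry for selection and
#'   validation.
#' @param esom Logical: train the ESOM/U-matrix stage (the costly part of
#'   the structure scan).
#' @param esom_rows,esom_cols,esom_epochs ESOM geometry.
#' @param correction Multiplicity correction for the marker screen.
#' @param enrichment_class Lipid class tested for over-representation among
#'   the sparse markers.
#' @param rfe_step RFE elimination fraction.
#' @param master_seed Master seed for all stages.
#' @param out_dir Optional directory; when given, artifacts are written as
#'   CSV/JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = synthetic_spec(),
                            values_path = NULL, metadata_path = NULL,
                            annotation_path = NULL,
                            tasks = c("timepoint", "neuropathy"),
                            holdout_fraction = 0.2,
                            missing_threshold = 0.2,
                            n_splits = 5L, n_repeats = 20L,
                            esom = TRUE, esom_rows = 50L, esom_cols = 80L,
                            esom_epochs = 20L,
                            correction = "BH",
                            enrichment_class = "sphingolipid",
                            rfe_step = 0.1,
                            master_seed = 42L,
                            out_dir = NULL) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_lipidmoe("holdout_fraction must be in (0, 1): validation is undefined without a holdout",
                  "lipidmoe_parameter_error")
  }
  structure(
    list(spec = spec, values_path = values_path,
         metadata_path = metadata_path, annotation_path = annotation_path,
         tasks = match.arg(tasks, several.ok = TRUE),
         holdout_fraction = holdout_fraction,
         missing_threshold = missing_threshold,
         n_splits = as.integer(n_splits), n_repeats = as.integer(n_repeats),
         esom = isTRUE(esom), esom_rows = as.integer(esom_rows),
         esom_cols = as.integer(esom_cols),
         esom_epochs = as.integer(esom_epochs),
         correction = correction, enrichment_class = enrichment_class,
         rfe_step = rfe_step, master_seed = as.integer(master_seed),
         out_dir = out_dir),
    class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$spec <- unclass(lst$spec)
  yaml::write_yaml(lst, path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  spec <- do.call(synthetic_spec, lst$spec)
  lst$spec <- NULL
  do.call(pipeline_config, c(list(spec = spec), lst))
}

#' Run the full analysis pipeline
#'
#' Executes all stages on simulated (or read) data. For each task:
#' a subject-grouped holdout is split off, classifiers are tuned, the
#' mixture-of-experts selection distills reduced and sparse marker sets,
#' and the sets are validated on the holdout with real and permuted
#' training labels. If every family's balanced-accuracy CI for a task
#' contains chance, multivariate selection is not trusted for that task
#' and selection falls back to the univariate experts only (effect size,
#' FPR, FWE), mirroring the handling of weakly learnable tasks.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with the preprocessed dataset,
#'   structure scan (`pca`, `esom`, `umatrix`, `clusters`, association
#'   test), and per-task results (tally, validation reports, marker
#'   statistics, enrichment), plus `seeds` used per stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  ms <- config$master_seed
  seeds <- list(simulate = derive_seed(ms, "simulate"),
                preprocess = derive_seed(ms, "preprocess"),
                structure = derive_seed(ms, "structure"),
                holdout = derive_seed(ms, "holdout"),
                tune = derive_seed(ms, "tune"),
                moe = derive_seed(ms, "moe"),
                validate = derive_seed(ms, "validate"))

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$values_path)) {
    raw <- read_lipid_dataset(config$values_path, config$metadata_path,
                              config$annotation_path)
  } else {
    spec <- config$spec
    spec$seed <- seeds$simulate
    sim <- generate_lipidomics(spec)
    raw <- sim$dataset
    truth <- sim$truth
  }

  # --- preprocessing ------------------------------------------------------
  prep <- preprocess(raw, threshold = config$missing_threshold,
                     seed = seeds$preprocess)
  ds <- prep$dataset

  # --- unsupervised structure --------------------------------------------
  ds_all_std <- z_standardize(ds)
  pca <- pca_structure(ds_all_std)
  structure_res <- list(pca = pca)
  if (config$esom) {
    model <- train_esom(ds_all_std, rows = config$esom_rows,
                        cols = config$esom_cols,
                        epochs = config$esom_epochs, seed = seeds$structure)
    bmus <- best_matching_units(model, ds_all_std)
    um <- umatrix(model)
    clusters <- tryCatch(extract_clusters(um, bmus, n_clusters = 2L),
                         lipidmoe_clustering_failure = function(e) NULL)
    assoc <- NULL
    if (!is.null(clusters)) {
      assoc <- tryCatch(
        cluster_class_association(clusters,
                                  make_labeling(ds, "timepoint")),
        lipidmoe_error = function(e) NULL)
    }
    structure_res <- c(structure_res,
                       list(esom = model, umatrix = um, bmus = bmus,
                            clusters = clusters, association = assoc))
  }

  # --- per-task supervised analysis --------------------------------------
  task_results <- list()
  for (task in config$tasks) {
    labeling <- make_labeling(ds, task)
    split <- split_holdout(ds, labeling, fraction = config$holdout_fraction,
                           seed = derive_seed(seeds$holdout, task))
    train <- z_standardize(split$train)
    # holdout scaled with training statistics
    holdout <- split$holdout
    mu <- attr(train, "standardization_means")
    sds <- attr(train, "standardization_sds")
    holdout$values <- sweep(sweep(holdout$values, 2L, mu, `-`), 2L, sds, `/`)
    holdout$standardized <- TRUE

    lab_tr <- make_labeling(train, task)
    tuned <- tune_classifiers(train, lab_tr,
                              seed = derive_seed(seeds$tune, task))
    tally <- run_moe(train, lab_tr, tuned = tuned,
                     n_splits = config$n_splits, n_repeats = config$n_repeats,
                     seed = derive_seed(seeds$moe, task),
                     rfe_step = config$rfe_step)
    sets <- list(full = colnames(train$values),
                 reduced = tally$reduced_set, sparse = tally$sparse_set)
    reports <- list()
    for (set_name in names(sets)) {
      if (!length(sets[[set_name]])) next
      reports[[set_name]] <- validate(
        train, holdout, labeling_task = task, feature_set = sets[[set_name]],
        tuned = tuned, n_splits = config$n_splits,
        n_repeats = config$n_repeats,
        seed = derive_seed(seeds$validate, paste0(task, set_name)))
    }
    reports$reduced_permuted <- validate(
      train, holdout, labeling_task = task, feature_set = sets$reduced,
      tuned = tuned, n_splits = config$n_splits,
      n_repeats = config$n_repeats,
      seed = derive_seed(seeds$validate, paste0(task, "perm")),
      permute = TRUE)

    # fallback: when no family separates from chance, multivariate selector
    # votes are not interpretable; univariate experts only
    ba <- dplyr::filter(reports$reduced$summary,
                        .data$metric == "balanced_accuracy")
    fallback <- !any(ba$separated_from_chance)
    if (fallback) {
      uni <- default_ensemble() |>
        dplyr::filter(.data$kind %in% c("cohens_d", "fpr", "fwe"))
      tally <- run_moe(train, lab_tr, ensemble = uni, tuned = tuned,
                       n_splits = config$n_splits,
                       n_repeats = config$n_repeats,
                       seed = derive_seed(seeds$moe, paste0(task, "uni")),
                       rfe_step = config$rfe_step)
    }

    markers <- if (length(tally$sparse_set)) {
      marker_group_tests(ds, labeling, features = tally$sparse_set,
                         correction = config$correction)
    } else NULL
    enrichment <- NULL
    if (length(tally$sparse_set) &&
        any(ds$features$feature_class %in% config$enrichment_class)) {
      enrichment <- tryCatch(
        class_enrichment(tally$sparse_set, ds$features,
                         config$enrichment_class),
        lipidmoe_error = function(e) NULL)
    }
    task_results[[task]] <- list(
      tally = tally, sets = sets, reports = reports,
      univariate_fallback = fallback, markers = markers,
      enrichment = enrichment, holdout_subjects = split$holdout_subjects)
  }

  result <- structure(
    list(config = config, seeds = seeds, truth = truth, dataset = ds,
         preprocessing = prep[c("transform_report", "report")],
         structure = structure_res, tasks = task_results),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d samples x %d features, tasks: %s\n",
              nrow(x$dataset$values), ncol(x$dataset$values),
              paste(names(x$tasks), collapse = ", ")))
  for (task in names(x$tasks)) {
    tr <- x$tasks[[task]]
    cat(sprintf("  %s: reduced %d, sparse %d%s\n", task,
                length(tr$sets$reduced), length(tr$sets$sparse),
                if (tr$univariate_fallback) " (univariate fallback)" else ""))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (task in names(result$tasks)) {
    tr <- result$tasks[[task]]
    readr::write_csv(tidy(tr$tally), file.path(dir, paste0(task, "_tally.csv")))
    jsonlite::write_json(tr$sets, file.path(dir, paste0(task, "_sets.json")),
                         auto_unbox = FALSE, pretty = TRUE)
    val <- purrr::imap_dfr(tr$reports,
                           ~dplyr::mutate(.x$summary, block = .y))
    readr::write_csv(val, file.path(dir, paste0(task, "_validation.csv")))
    if (!is.null(tr$markers)) {
      readr::write_csv(tr$markers, file.path(dir, paste0(task, "_markers.csv")))
    }
  }
  jsonlite::write_json(result$seeds, file.path(dir, "seeds.json"),
                       auto_unbox = TRUE)
  invisible(result)
}
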