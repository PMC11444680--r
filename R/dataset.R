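# Core dataset container -------------------------------------------------

#' Construct a lipidomics dataset
#'
#' Bundles a samples x lipid-mediators concentration matrix with the sample
#' metadata (subject pairing, sampling timepoint, neuropathy status) and an
#' optional per-feature lipid-class annotation. All downstream stages of the
#' pipeline consume this container.
#'
#' Invariants enforced at construction:
#' * sample ids and feature names are unique and consistent with the matrix,
#' * a subject contributes at most one sample per timepoint,
#' * neuropathy status is only non-`"unknown"` on day-2 samples (a day-1 row
#'   never carries its subject's eventual label directly).
#'
#' @param values Numeric matrix, rows = samples, columns = lipid mediators.
#'   Missing concentrations are `NA`.
#' @param samples Data frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (`"day1"`/`"day2"`), `neuropathy` (`"yes"`/`"no"`/`"unknown"`).
#' @param features Optional data frame with columns `feature_name` and
#'   `feature_class`; defaults to unannotated features.
#' @param log_transformed,standardized Logical state flags set by the
#'   preprocessing stage.
#' @return An object of class `lipid_dataset`.
#' @export
lipid_dataset <- function(values, samples, features = NULL,
                          log_transformed = FALSE, standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "subject_id", "timepoint", "neuropathy")
  if (!all(req %in% names(samples))) {
    stop_lipidmoe(paste0("sample metadata must have columns ",
                         paste(req, collapse = ", ")), "lipidmoe_format_error")
  }
  samples <- dplyr::mutate(samples, dplyr::across(dplyr::all_of(req), as.character))
  if (is.null(features)) {
    features <- tibble::tibble(feature_name = colnames(values),
                               feature_class = NA_character_)
  }
  features <- tibble::as_tibble(features)
  if (!"feature_class" %in% names(features)) features$feature_class <- NA_character_

  if (nrow(values) != nrow(samples)) {
    stop_lipidmoe("row count of values must equal number of metadata rows",
                  "lipidmoe_format_error")
  }
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (is.null(colnames(values))) colnames(values) <- features$feature_name
  if (anyDuplicated(samples$sample_id)) {
    stop_lipidmoe("duplicated sample id", "lipidmoe_format_error")
  }
  if (anyDuplicated(features$feature_name)) {
    stop_lipidmoe("duplicated feature name", "lipidmoe_format_error")
  }
  if (!identical(rownames(values), samples$sample_id)) {
    if (!setequal(rownames(values), samples$sample_id)) {
      stop_lipidmoe("sample ids of values and metadata do not match",
                    "lipidmoe_join_error")
    }
    values <- values[samples$sample_id, , drop = FALSE]
  }
  if (ncol(values) != nrow(features) ||
      !setequal(colnames(values), features$feature_name)) {
    stop_lipidmoe("feature names of values and annotation do not match",
                  "lipidmoe_join_error")
  }
  features <- features[match(colnames(values), features$feature_name), ]
  if (!all(samples$timepoint %in% c("day1", "day2"))) {
    stop_lipidmoe("timepoint must be 'day1' or 'day2'", "lipidmoe_format_error")
  }
  if (!all(samples$neuropathy %in% c("yes", "no", "unknown"))) {
    stop_lipidmoe("neuropathy must be 'yes', 'no' or 'unknown'",
                  "lipidmoe_format_error")
  }
  dup <- samples |>
    dplyr::count(.data$subject_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_lipidmoe(paste0("subject(s) with two samples at one timepoint: ",
                         paste(unique(dup$subject_id), collapse = ", ")),
                  "lipidmoe_consistency_error")
  }
  if (any(samples$timepoint == "day1" & samples$neuropathy != "unknown")) {
    stop_lipidmoe("day-1 samples must carry neuropathy = 'unknown'",
                  "lipidmoe_consistency_error")
  }
  structure(
    list(values = values, samples = samples, features = features,
         log_transformed = isTRUE(log_transformed),
         standardized = isTRUE(standardized)),
    class = "lipid_dataset"
  )
}

#' @export
print.lipid_dataset <- function(x, ...) {
  cat(sprintf("<lipid_dataset> %d samples x %d lipid mediators\n",
              nrow(x$values), ncol(x$values)))
  tp <- table(x$samples$timepoint)
  cat(sprintf("  timepoints: %s\n",
              paste(sprintf("%s=%d", names(tp), tp), collapse = ", ")))
  np <- table(x$samples$neuropathy)
  cat(sprintf("  neuropathy: %s\n",
              paste(sprintf("%s=%d", names(np), np), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%  log: %s  standardized: %s\n",
              100 * mean(is.na(x$values)), x$log_transformed, x$standardized))
  invisible(x)
}

#' @export
dim.lipid_dataset <- function(x) dim(x$values)

#' Tidy a lipid dataset into long format
#'
#' @param x A [lipid_dataset].
#' @param ... Unused.
#' @return A tibble with one row per (sample, feature) cell: sample metadata,
#'   `feature_name`, `feature_class` and `value`.
#' @export
tidy.lipid_dataset <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_name",
                        values_to = "value")
  long |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::left_join(x$features, by = "feature_name") |>
    dplyr::select("sample_id", "subject_id", "timepoint", "neuropathy",
                  "feature_name", "feature_class", "value")
}

# Readers / writers ------------------------------------------------------

read_delim_auto <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE)
}

parse_numeric_cells <- function(df, path) {
  mat <- as.matrix(df)
  missing_token <- mat == "" | toupper(mat) == "NA"
  suppressWarnings(num <- as.numeric(mat))
  bad <- !missing_token & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_lipidmoe(
      sprintf("non-numeric cell '%s' in %s at row %d, column '%s'",
              mat[bad][1L], basename(path), idx[["row"]],
              colnames(mat)[idx[["col"]]]),
      "lipidmoe_format_error")
  }
  num[missing_token] <- NA_real_
  matrix(num, nrow = nrow(mat), dimnames = dimnames(mat))
}

#' Read a lipidomics dataset from delimited tables
#'
#' Reads the quantified concentration table (first column = sample id, one
#' column per lipid mediator), the sample metadata table and an optional
#' lipid-class annotation table. Delimiter is inferred from the file
#' extension (`.tsv` = tab, otherwise comma) unless given. Empty cells and
#' `"NA"` (case-insensitive) are parsed as missing; any other non-numeric
#' cell is an error naming the offending row and column.
#'
#' @param values_path,metadata_path,annotation_path File paths; the
#'   annotation is optional. Metadata needs columns `sample_id`,
#'   `subject_id`, `timepoint`, `neuropathy`; the annotation needs
#'   `feature_name`, `feature_class`.
#' @param delim Optional explicit delimiter for all files.
#' @return A validated [lipid_dataset].
#' @export
read_lipid_dataset <- function(values_path, metadata_path,
                               annotation_path = NULL, delim = NULL) {
  vals_df <- read_delim_auto(values_path, delim)
  meta <- read_delim_auto(metadata_path, delim)
  id_col <- names(vals_df)[1L]
  ids <- vals_df[[id_col]]
  if (anyDuplicated(ids)) {
    stop_lipidmoe(sprintf("duplicated sample id '%s' in %s",
                          ids[duplicated(ids)][1L], basename(values_path)),
                  "lipidmoe_format_error")
  }
  if (!setequal(ids, meta$sample_id)) {
    missing_ids <- setdiff(union(ids, meta$sample_id),
                           intersect(ids, meta$sample_id))
    stop_lipidmoe(sprintf("sample id mismatch between values and metadata: %s",
                          paste(missing_ids, collapse = ", ")),
                  "lipidmoe_join_error")
  }
  values <- parse_numeric_cells(vals_df[-1L], values_path)
  rownames(values) <- ids
  features <- NULL
  if (!is.null(annotation_path)) {
    features <- read_delim_auto(annotation_path, delim)
  }
  lipid_dataset(values, meta, features)
}

#' Write a lipidomics dataset to delimited tables
#'
#' Inverse of [read_lipid_dataset()]: finite values round-trip bit-identically
#' (written with full precision) and the missingness pattern is preserved.
#'
#' @param ds A [lipid_dataset].
#' @param values_path,metadata_path,annotation_path Output paths; annotation
#'   written only if a path is given.
#' @return `ds`, invisibly.
#' @export
write_lipid_dataset <- function(ds, values_path, metadata_path,
                                annotation_path = NULL) {
  vals <- tibble::as_tibble(ds$values, rownames = "sample_id")
  readr::write_csv(vals, values_path, na = "NA")
  readr::write_csv(ds$samples, metadata_path, na = "NA")
  if (!is.null(annotation_path)) {
    readr::write_csv(ds$features, annotation_path, na = "NA")
  }
  invisible(ds)
}

# Class labelings --------------------------------------------------------

#' Build a binary classification labeling from a dataset
#'
#' The `timepoint` task labels every sample as pre- (`day1`) or
#' post-therapy (`day2`). The `neuropathy` task is defined on day-2 samples
#' only, labeled `yes`/`no`; day-1 samples are excluded because their
#' neuropathy status is structurally unknown at sampling time.
#'
#' @param ds A [lipid_dataset].
#' @param task `"timepoint"` or `"neuropathy"`.
#' @return A `class_labeling`: tibble with columns `sample_id`, `subject_id`
#'   and `label` (factor; second level = positive class `day2`/`yes`), with
#'   attribute `task`.
#' @export
make_labeling <- function(ds, task = c("timepoint", "neuropathy")) {
  task <- match.arg(task)
  if (task == "timepoint") {
    tab <- ds$samples |>
      dplyr::transmute(.data$sample_id, .data$subject_id,
                       label = factor(.data$timepoint, levels = c("day1", "day2")))
  } else {
    tab <- ds$samples |>
      dplyr::filter(.data$timepoint == "day2") |>
      dplyr::transmute(.data$sample_id, .data$subject_id,
                       label = factor(.data$neuropathy, levels = c("no", "yes")))
  }
  tab <- dplyr::filter(tab, !is.na(.data$label))
  if (dplyr::n_distinct(tab$label) < 2L) {
    stop_lipidmoe(sprintf("task '%s' is degenerate: only one class present", task),
                  "lipidmoe_degenerate_task_error")
  }
  structure(tab, task = task, class = c("class_labeling", class(tab)))
}

labeling_task <- function(labeling) attr(labeling, "task")

# matrix + factor view used by the model-fitting stages
labeling_xy <- function(ds, labeling, feature_set = NULL) {
  feature_set <- feature_set %||% colnames(ds$values)
  x <- ds$values[labeling$sample_id, feature_set, drop = FALSE]
  list(x = x, y = droplevels(labeling$label), subject = labeling$subject_id)
}
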