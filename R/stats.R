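# Classical statistics: Kruskal-Wallis, Fisher, enrichment ---------------

#' Kruskal-Wallis rank-sum comparison
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on g - 1 degrees of freedom (delegating to [stats::kruskal.test()]).
#'
#' @param groups A list of two or more numeric vectors, one per group.
#' @return A tibble: `method`, `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(!lengths(groups))) {
    stop_lipidmoe("every group must be nonempty", "lipidmoe_input_error")
  }
  if (sum(lengths(groups)) < 3L) {
    stop_lipidmoe("Kruskal-Wallis needs at least 3 observations in total",
                  "lipidmoe_input_error")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- kruskal.test(x, g)
  tibble::tibble(method = "kruskal_wallis",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up FDR adjustment by default, with
#' Bonferroni-Holm available; both are monotone, so no adjusted value falls
#' below its raw p-value.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"holm"`.
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_p <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_lipidmoe("p-values must lie in [0, 1]", "lipidmoe_domain_error")
  }
  p.adjust(p, method = method)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided exact p (summing hypergeometric probabilities no larger than
#' the observed table's), conditional maximum-likelihood odds ratio, and a
#' 95% confidence interval by inverting the exact conditional test
#' (delegating to [stats::fisher.test()]). Zero cells yield an odds ratio
#' of 0 or Inf with the corresponding one-sided bound.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return A tibble: `method`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    stop_lipidmoe("fisher_exact needs a 2 x 2 table of nonnegative integers",
                  "lipidmoe_domain_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_lipidmoe("degenerate table: a margin is zero",
                  "lipidmoe_degenerate_table_error")
  }
  res <- fisher.test(table)
  tibble::tibble(method = "fisher_exact",
                 odds_ratio = unname(res$estimate),
                 ci_low = res$conf.int[1L],
                 ci_high = res$conf.int[2L],
                 p_value = res$p.value)
}

#' Lipid-class over-representation of a selected feature set
#'
#' Fisher's exact test of the 2 x 2 table (in-class vs out-of-class) x
#' (selected vs not selected) over an annotated feature universe — e.g. are
#' sphingolipids over-represented among the markers the consensus selection
#' retained?
#'
#' @param selected Character vector of selected feature names.
#' @param background Data frame with columns `feature_name`, `feature_class`
#'   covering the whole annotated universe.
#' @param class_label The lipid class tested for enrichment.
#' @return A tibble as [fisher_exact()], with the table as attribute
#'   `"table"` and the class label in `method`.
#' @export
class_enrichment <- function(selected, background, class_label) {
  background <- tibble::as_tibble(background)
  missing_sel <- setdiff(selected, background$feature_name)
  if (length(missing_sel)) {
    stop_lipidmoe(paste0("selected features without annotation: ",
                         paste(missing_sel, collapse = ", ")),
                  "lipidmoe_annotation_error")
  }
  in_class <- background$feature_name[background$feature_class %in% class_label]
  out_class <- setdiff(background$feature_name, in_class)
  tab <- matrix(c(
    length(intersect(in_class, selected)),
    length(intersect(out_class, selected)),
    length(setdiff(in_class, selected)),
    length(setdiff(out_class, selected))), nrow = 2L, byrow = TRUE,
    dimnames = list(c("selected", "not_selected"),
                    c("in_class", "out_class")))
  res <- fisher_exact(tab)
  res$method <- paste0("enrichment:", class_label)
  attr(res, "table") <- tab
  res
}

#' Per-feature Kruskal-Wallis screen of a marker panel
#'
#' Compares every feature of a panel between the two classes of a labeling
#' and corrects the p-values for multiplicity.
#'
#' @param ds A [lipid_dataset].
#' @param labeling A `class_labeling`.
#' @param features Feature names to screen (default: all).
#' @param correction `"BH"` or `"holm"`.
#' @return A tibble: `feature`, `statistic`, `p_value`, `p_adjusted`,
#'   ordered by `p_value`.
#' @export
marker_group_tests <- function(ds, labeling, features = NULL,
                               correction = c("BH", "holm")) {
  correction <- match.arg(correction)
  features <- features %||% colnames(ds$values)
  xy <- labeling_xy(ds, labeling, features)
  res <- purrr::map_dfr(features, function(f) {
    groups <- split(xy$x[, f], xy$y)
    kw <- kruskal_wallis(unname(groups))
    tibble::tibble(feature = f, statistic = kw$statistic, p_value = kw$p_value)
  })
  res$p_adjusted <- adjust_p(res$p_value, correction)
  dplyr::arrange(res, .data$p_value)
}
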