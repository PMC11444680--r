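# Computed ABC analysis ---------------------------------------------------

#' ABC curve of a nonnegative importance vector
#'
#' Items are sorted by value in decreasing order (ties keep their original
#' order) and the curve pairs the effort fraction `x_i = i/n` with the
#' cumulative yield fraction `y_i = sum(first i values) / sum(all values)`.
#'
#' @param values Nonnegative numeric vector; names are kept as item labels.
#' @return A tibble with columns `item`, `value`, `x`, `y` in curve order.
#' @export
abc_curve <- function(values) {
  check_abc_input(values)
  items <- names(values) %||% paste0("item", seq_along(values))
  ord <- order(-values, seq_along(values)) # ties keep original positions
  v <- values[ord]
  tibble::tibble(item = items[ord], value = unname(v),
                 x = seq_along(v) / length(v),
                 y = cumsum(as.numeric(v)) / sum(as.numeric(v)))
}

check_abc_input <- function(values) {
  if (!length(values)) {
    stop_lipidmoe("empty input", "lipidmoe_domain_error")
  }
  if (any(is.na(values)) || any(values < 0)) {
    stop_lipidmoe("ABC analysis needs nonnegative, non-missing values",
                  "lipidmoe_domain_error")
  }
  if (all(values == 0)) {
    stop_lipidmoe("all values are zero: ABC curve undefined",
                  "lipidmoe_degenerate_input_error")
  }
  invisible(values)
}

#' Computed ABC (cABC) categorization
#'
#' Partitions a nonnegative importance vector into the "important few"
#' (category A), the middle ground (B) and the "trivial many" (C) using the
#' geometry of the empirical, piecewise-linear ABC curve:
#'
#' * the A|B boundary is the curve point closest (Euclidean) to the ideal
#'   point (0, 1), i.e. maximal yield for minimal effort;
#' * the B|C boundary is the last point before the curve's segment slope
#'   falls below 1, the break-even point where one additional item stops
#'   contributing more than its nominal share;
#' * if break-even precedes the A|B point, B is empty (`B|C = A|B`).
#'
#' An all-equal input carries no concentration signal: every item is put in
#' category C and the result is flagged degenerate. Equal values straddling
#' a boundary are split deterministically by original order, with a warning.
#'
#' @param values Nonnegative numeric vector (optionally named).
#' @return A `cabc_result`: list with `curve` (see [abc_curve()]),
#'   `ab_index`, `bc_index`, `categories` (tibble `item`, `value`,
#'   `category`) and `degenerate`.
#' @export
cabc_categorize <- function(values) {
  check_abc_input(values)
  n <- length(values)
  curve <- abc_curve(values)
  if (n == 1L) {
    return(new_cabc_result(curve, 1L, 1L, degenerate = FALSE))
  }
  if (length(unique(values)) == 1L) {
    # no concentration structure: all items are "trivial many"
    return(new_cabc_result(curve, 0L, 0L, degenerate = TRUE))
  }
  d2 <- curve$x^2 + (curve$y - 1)^2
  ab <- which.min(d2)
  slopes <- diff(c(0, curve$y)) / diff(c(0, curve$x)) # segment i ends at point i
  below <- which(slopes < 1)
  bc <- if (length(below)) below[1L] - 1L else n
  if (bc < ab) bc <- ab
  res <- new_cabc_result(curve, as.integer(ab), as.integer(bc),
                         degenerate = FALSE)
  warn_boundary_ties(curve, ab, bc)
  res
}

new_cabc_result <- function(curve, ab_index, bc_index, degenerate) {
  n <- nrow(curve)
  category <- rep("C", n)
  if (!degenerate) {
    if (ab_index >= 1L) category[seq_len(ab_index)] <- "A"
    if (bc_index > ab_index) category[(ab_index + 1L):bc_index] <- "B"
  }
  structure(
    list(curve = curve, ab_index = ab_index, bc_index = bc_index,
         categories = tibble::tibble(item = curve$item, value = curve$value,
                                     category = category),
         degenerate = degenerate),
    class = "cabc_result")
}

warn_boundary_ties <- function(curve, ab, bc) {
  n <- nrow(curve)
  for (b in unique(c(ab, bc))) {
    if (b >= 1L && b < n && curve$value[b] == curve$value[b + 1L]) {
      warn(sprintf(
        "tied values straddle an ABC boundary (items '%s' and '%s'); split by original order",
        curve$item[b], curve$item[b + 1L]),
        class = "lipidmoe_boundary_tie_warning")
    }
  }
}

#' @export
print.cabc_result <- function(x, ...) {
  tab <- table(factor(x$categories$category, levels = c("A", "B", "C")))
  cat(sprintf("<cabc_result> %d items: A=%d, B=%d, C=%d%s\n",
              nrow(x$categories), tab[["A"]], tab[["B"]], tab[["C"]],
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Members of one ABC category
#'
#' @param x A `cabc_result`.
#' @param category `"A"`, `"B"` or `"C"`.
#' @return Character vector of item labels.
#' @export
abc_members <- function(x, category = "A") {
  x$categories$item[x$categories$category == category]
}

#' Nested (recursive) cABC analysis
#'
#' Repeats the cABC analysis on the items of the previous category A,
#' distilling the importance vector to a sparser core set. Recursion stops
#' when `depth` is reached or category A stops shrinking. Items removed at
#' an earlier stage keep that stage's category; the final category A is the
#' surviving core.
#'
#' @param values Nonnegative numeric vector (optionally named).
#' @param depth Number of cABC passes (`depth = 1` equals
#'   [cabc_categorize()]).
#' @return A `cabc_result` whose `curve` is the first-pass curve and whose
#'   `categories` reflect the nested assignment.
#' @export
nested_cabc <- function(values, depth = 2L) {
  stopifnot(depth >= 1L)
  first <- cabc_categorize(values)
  if (first$degenerate) return(first)
  items <- names(values) %||% paste0("item", seq_along(values))
  names(values) <- items
  cat_map <- setNames(first$categories$category, first$categories$item)
  a_set <- abc_members(first, "A")
  d <- 1L
  while (d < depth && length(a_set) > 1L) {
    sub <- cabc_categorize(values[a_set])
    if (sub$degenerate) break
    new_a <- abc_members(sub, "A")
    if (length(new_a) == length(a_set)) break
    for (cc in c("B", "C")) cat_map[abc_members(sub, cc)] <- cc
    a_set <- new_a
    d <- d + 1L
  }
  out <- first
  out$categories$category <- unname(cat_map[out$categories$item])
  out$ab_index <- length(a_set)
  out$bc_index <- max(out$ab_index,
                      sum(out$categories$category %in% c("A", "B")))
  out
}

#' @export
tidy.cabc_result <- function(x, ...) {
  dplyr::left_join(x$categories,
                   dplyr::select(x$curve, "item", "x", "y"),
                   by = "item")
}

#' Plot an ABC curve with category boundaries
#'
#' @param object A `cabc_result`.
#' @param ... Unused.
#' @return A ggplot: the cumulative ABC curve, the identity line, and the
#'   A|B and B|C boundaries.
#' @export
autoplot.cabc_result <- function(object, ...) {
  curve <- object$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_point(size = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "fraction of items (effort)",
                  y = "cumulative fraction of total value (yield)",
                  title = "ABC curve") +
    ggplot2::theme_minimal()
  if (!object$degenerate && object$ab_index >= 1L) {
    p <- p +
      ggplot2::geom_vline(xintercept = curve$x[object$ab_index],
                          colour = "#b2182b") +
      ggplot2::geom_vline(xintercept = curve$x[object$bc_index],
                          colour = "#b2182b", linetype = "dashed")
  }
  p
}
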