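# Emergent self-organizing map with U-matrix clustering ------------------

# toroidal squared grid distance between neuron coordinate sets
toroidal_dist2 <- function(r1, c1, r2, c2, rows, cols) {
  dr <- abs(r1 - r2); dr <- pmin(dr, rows - dr)
  dc <- abs(c1 - c2); dc <- pmin(dc, cols - dc)
  dr^2 + dc^2
}

# the 8 toroidal neighbors of each neuron (row-major indexing)
toroidal_neighbors <- function(rows, cols) {
  coords <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lapply(seq_len(rows * cols), function(i) {
    r <- ((coords$row[i] - 1 + offs$dr) %% rows) + 1
    c <- ((coords$col[i] - 1 + offs$dc) %% cols) + 1
    unique((r - 1) * cols + c)
  })
}

#' Train an emergent self-organizing map on a toroidal grid
#'
#' A large SOM (default 50 x 80 = 4000 neurons, far more neurons than
#' samples) on a torus, so cluster structure can emerge free of border
#' effects. Weights are initialized by sampling data rows with replacement;
#' training is online: per epoch the samples are presented in shuffled
#' order, each sample pulls its best matching unit (BMU) and, with a
#' Gaussian kernel over toroidal grid distance, its neighborhood towards
#' itself. Learning rate and radius decay linearly from
#' `(alpha_start, max(rows, cols)/2)` to `(alpha_end, 1)` over all steps.
#'
#' @param ds A standardized [lipid_dataset] (n >= 2).
#' @param rows,cols Grid dimensions (at least 2 x 2).
#' @param epochs Training epochs.
#' @param alpha_start,alpha_end Learning-rate schedule.
#' @param seed Integer seed; training is deterministic given it.
#' @return An `esom_model`: list with `weights` (neurons x features,
#'   row-major grid order), `rows`, `cols`, `epochs`, `seed`.
#' @export
train_esom <- function(ds, rows = 50L, cols = 80L, epochs = 20L,
                       alpha_start = 0.5, alpha_end = 0.01, seed = 1L) {
  if (rows < 2L || cols < 2L) {
    stop_lipidmoe("ESOM grid must be at least 2 x 2", "lipidmoe_spec_error")
  }
  x <- ds$values
  if (nrow(x) < 2L) {
    stop_lipidmoe("ESOM training needs at least 2 samples", "lipidmoe_size_error")
  }
  n_neurons <- rows * cols
  coords <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  radius_start <- max(rows, cols) / 2
  radius_end <- 1
  total_steps <- epochs * nrow(x)

  withr::with_seed(seed, {
    w <- x[sample.int(nrow(x), n_neurons, replace = TRUE), , drop = FALSE]
    rownames(w) <- NULL
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nrow(x))) {
        frac <- step / max(total_steps - 1L, 1L)
        alpha <- alpha_start + (alpha_end - alpha_start) * frac
        radius <- radius_start + (radius_end - radius_start) * frac
        xi <- x[i, ]
        d2 <- rowSums(sweep(w, 2L, xi, `-`)^2)
        bmu <- which.min(d2)
        g2 <- toroidal_dist2(coords$row, coords$col,
                             coords$row[bmu], coords$col[bmu], rows, cols)
        h <- alpha * exp(-g2 / (2 * radius^2))
        active <- h > 1e-4 # negligible updates skipped
        w[active, ] <- w[active, , drop = FALSE] +
          h[active] * sweep(w[active, , drop = FALSE], 2L, xi, function(a, b) b - a)
        step <- step + 1L
      }
    }
    structure(list(weights = w, rows = as.integer(rows),
                   cols = as.integer(cols), epochs = as.integer(epochs),
                   feature_names = colnames(x), seed = as.integer(seed)),
              class = "esom_model")
  })
}

#' @export
print.esom_model <- function(x, ...) {
  cat(sprintf("<esom_model> %d x %d toroidal grid (%d neurons), %d features, %d epochs\n",
              x$rows, x$cols, x$rows * x$cols, ncol(x$weights), x$epochs))
  invisible(x)
}

#' Best matching units of samples on a trained ESOM
#'
#' @param model An `esom_model`.
#' @param ds A [lipid_dataset] with the model's features.
#' @return A tibble with `sample_id`, `neuron` (row-major index), `row`,
#'   `col`, `distance`. Ties go to the smallest row-major index.
#' @export
best_matching_units <- function(model, ds) {
  x <- ds$values
  if (ncol(x) != ncol(model$weights) ||
      !identical(colnames(x), model$feature_names)) {
    stop_lipidmoe("feature dimensions of model and data do not match",
                  "lipidmoe_shape_error")
  }
  w2 <- rowSums(model$weights^2)
  cross <- x %*% t(model$weights)
  d2 <- sweep(-2 * cross, 2L, w2, `+`) + rowSums(x^2)
  bmu <- apply(d2, 1L, which.min) # which.min takes the first = smallest index
  tibble::tibble(
    sample_id = rownames(x),
    neuron = as.integer(bmu),
    row = (bmu - 1L) %/% model$cols + 1L,
    col = (bmu - 1L) %% model$cols + 1L,
    distance = sqrt(pmax(d2[cbind(seq_len(nrow(x)), bmu)], 0)))
}

#' U-matrix of a trained ESOM
#'
#' The U-height of a neuron is the mean high-dimensional (Euclidean)
#' distance of its weight vector to its 8 immediate toroidal neighbors;
#' ridges of large heights mark cluster borders.
#'
#' @param model An `esom_model`.
#' @return A `lipid_umatrix`: list with `heights` (numeric, row-major),
#'   `rows`, `cols`.
#' @export
umatrix <- function(model) {
  nb <- toroidal_neighbors(model$rows, model$cols)
  w <- model$weights
  heights <- vapply(seq_along(nb), function(i) {
    mean(sqrt(rowSums(sweep(w[nb[[i]], , drop = FALSE], 2L, w[i, ], `-`)^2)))
  }, numeric(1))
  structure(list(heights = heights, rows = model$rows, cols = model$cols),
            class = "lipid_umatrix")
}

#' @export
print.lipid_umatrix <- function(x, ...) {
  cat(sprintf("<lipid_umatrix> %d x %d; height range [%.3g, %.3g]\n",
              x$rows, x$cols, min(x$heights), max(x$heights)))
  invisible(x)
}

#' Plot a U-matrix as a topographic height map
#'
#' @param object A `lipid_umatrix`.
#' @param bmus Optional BMU tibble from [best_matching_units()] to overlay.
#' @param ... Unused.
#' @return A ggplot tile map (dark = valleys/clusters, light = ridges).
#' @export
autoplot.lipid_umatrix <- function(object, bmus = NULL, ...) {
  df <- tibble::tibble(
    height = object$heights,
    row = rep(seq_len(object$rows), each = object$cols),
    col = rep(seq_len(object$cols), times = object$rows))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$height)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("#1a9850", "#fee08b", "#8c510a",
                                              "white")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "ESOM U-matrix", x = "column", y = "row") +
    ggplot2::theme_minimal()
  if (!is.null(bmus)) {
    p <- p + ggplot2::geom_point(data = bmus,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE, size = 1.5)
  }
  p
}

# connected components of a neuron subset under toroidal 8-adjacency
grid_components <- function(keep, rows, cols) {
  nb <- toroidal_neighbors(rows, cols)
  idx <- which(keep)
  if (!length(idx)) return(integer(rows * cols))
  edges <- do.call(rbind, lapply(idx, function(i) {
    j <- nb[[i]][keep[nb[[i]]]]
    if (length(j)) cbind(i, j) else NULL
  }))
  if (is.null(edges)) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(as.character(idx))
  } else {
    g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2L),
                                     directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(idx),
                                      igraph::V(g)$name))
  }
  comp <- igraph::components(g)$membership
  out <- integer(rows * cols)
  out[as.integer(names(comp))] <- comp
  out
}

#' Extract sample clusters from the U-matrix height field
#'
#' Watershed-style reading of the U-matrix: the height threshold starts just
#' below the highest ridge and is lowered (quantiles scanned from the top)
#' until the below-threshold neurons split into at least `n_clusters`
#' connected components (8-neighborhood on the torus) that contain BMUs —
#' the first split from above is the watershed between the deepest valleys.
#' The `n_clusters` components carrying the most samples become the cluster
#' cores; samples inherit the component of their BMU, and BMUs on ridges or
#' in smaller fragments join the nearest core by toroidal grid distance.
#'
#' @param um A `lipid_umatrix`.
#' @param bmus BMU tibble from [best_matching_units()].
#' @param n_clusters Target number of clusters.
#' @param quantiles Candidate threshold quantiles, scanned in order.
#' @return A tibble `sample_id`, `cluster` (integer). If no threshold
#'   yields `n_clusters` BMU-bearing components, a
#'   `lipidmoe_clustering_failure` condition is signalled.
#' @export
extract_clusters <- function(um, bmus, n_clusters = 2L,
                             quantiles = seq(0.05, 0.95, by = 0.05)) {
  if (n_clusters == 1L) {
    return(tibble::tibble(sample_id = bmus$sample_id, cluster = 1L))
  }
  if (diff(range(um$heights)) < .Machine$double.eps^0.5) {
    stop_lipidmoe("flat U-matrix: no ridge exists to split clusters",
                  "lipidmoe_clustering_failure")
  }
  rows <- um$rows; cols <- um$cols
  for (q in sort(quantiles, decreasing = TRUE)) {
    thr <- quantile(um$heights, q)
    keep <- um$heights <= thr
    comp <- grid_components(keep, rows, cols)
    bmu_comp <- comp[bmus$neuron]
    used <- sort(unique(bmu_comp[bmu_comp > 0L]))
    if (length(used) >= n_clusters) {
      # keep the n_clusters components carrying the most samples as cluster
      # cores; everything else (smaller fragments, ridge BMUs) joins the
      # nearest core by toroidal grid distance
      sizes <- vapply(used, function(cc) sum(bmu_comp == cc), integer(1))
      used <- used[order(-sizes)][seq_len(n_clusters)]
      comp_coords <- lapply(used, function(cc) which(comp == cc))
      cluster <- integer(nrow(bmus))
      for (s in seq_len(nrow(bmus))) {
        if (bmu_comp[s] %in% used) {
          cluster[s] <- match(bmu_comp[s], used)
        } else {
          r <- bmus$row[s]; cl <- bmus$col[s]
          dmin <- vapply(comp_coords, function(members) {
            mr <- (members - 1L) %/% cols + 1L
            mc <- (members - 1L) %% cols + 1L
            min(toroidal_dist2(mr, mc, r, cl, rows, cols))
          }, numeric(1))
          cluster[s] <- which.min(dmin)
        }
      }
      return(tibble::tibble(sample_id = bmus$sample_id, cluster = cluster))
    }
  }
  stop_lipidmoe(sprintf("could not form %d clusters at any threshold", n_clusters),
                "lipidmoe_clustering_failure")
}

#' Association between U-matrix clusters and a prior classing
#'
#' Fisher's exact test on the 2 x 2 cluster-by-class contingency table
#' (delegating to [fisher_exact()]); refuses more than two clusters, the
#' setting the ESOM reading targets.
#'
#' @param clusters Tibble `sample_id`, `cluster` from [extract_clusters()].
#' @param labeling A `class_labeling` from [make_labeling()].
#' @return A tibble as returned by [fisher_exact()], plus the table as
#'   attribute `"table"`.
#' @export
cluster_class_association <- function(clusters, labeling) {
  joined <- dplyr::inner_join(clusters, labeling, by = "sample_id")
  if (dplyr::n_distinct(joined$cluster) != 2L) {
    stop_lipidmoe("association test requires exactly 2 clusters",
                  "lipidmoe_contract_error")
  }
  tab <- table(joined$cluster, droplevels(joined$label))
  res <- fisher_exact(unclass(matrix(tab, 2L, 2L)))
  attr(res, "table") <- tab
  res
}
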