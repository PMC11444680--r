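# PCA structure ----------------------------------------------------------

test_that("PCA structure handles closed-form and oracle cases", {
  # two perfectly correlated standardized features -> eigenvalues {2, 0}
  set.seed(2)
  a <- rnorm(50)
  x <- scale(cbind(f1 = a, f2 = 2 * a + 3))
  ds <- matrix_dataset(x)
  p <- pca_structure(ds)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_identical(p$retained, 1L)
  expect_equal(p$explained_fraction, 1, tolerance = 1e-12)

  # block matrix: eigenvalues match an independent svd-based solver
  set.seed(3)
  z <- matrix(rnorm(200 * 4), 200, 4)
  z[, 2] <- z[, 1] * 0.8 + z[, 2] * 0.6
  z[, 4] <- z[, 3] * 0.8 + z[, 4] * 0.6
  ds2 <- matrix_dataset(scale(z))
  p2 <- pca_structure(ds2)
  sv <- svd(scale(z) / sqrt(nrow(z) - 1))$d^2 # svd route as oracle
  expect_equal(p2$eigenvalues, sv, tolerance = 1e-10)

  # independent standardized noise at large n: few eigenvalues exceed 1
  set.seed(4)
  noise <- matrix_dataset(scale(matrix(rnorm(4000 * 8), 4000, 8)))
  pn <- pca_structure(noise)
  expect_lte(length(pn$retained), 4L)

  expect_error(pca_structure(matrix_dataset(scale(matrix(rnorm(4), 2, 2)))),
               class = "lipidmoe_size_error")
})

test_that("eigenvalue bookkeeping: trace equals feature count", {
  sim <- generate_lipidomics(small_spec(seed = 6L))
  ds <- z_standardize(apply_power(sim$dataset, 0))
  p <- pca_structure(ds)
  expect_equal(sum(p$eigenvalues), ncol(ds$values), tolerance = 1e-8)
  expect_equal(p$explained_fraction,
               sum(p$eigenvalues[p$retained]) / ncol(ds$values),
               tolerance = 1e-12)
  expect_true(all(diff(p$eigenvalues) <= 1e-10))
  expect_true(all(p$importance >= 0))
  expect_gt(length(p$important_features), 0)
})

# ESOM / U-matrix ---------------------------------------------------------

test_that("toroidal neighborhoods have exactly 8 members with wrap-around", {
  nb <- lipidmoe:::toroidal_neighbors(5, 7)
  expect_length(nb, 35)
  expect_true(all(lengths(nb) == 8L))
  # corner neuron (row 1, col 1) wraps to the opposite edges
  corner <- nb[[1]]
  idx_of <- function(r, c, cols = 7) (r - 1) * cols + c
  expect_setequal(corner,
                  c(idx_of(5, 7), idx_of(5, 1), idx_of(5, 2),
                    idx_of(1, 7), idx_of(1, 2),
                    idx_of(2, 7), idx_of(2, 1), idx_of(2, 2)))
})

test_that("ESOM training is deterministic and collapses onto a single attractor", {
  x <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  colnames(x) <- paste0("f", 1:3)
  ds <- matrix_dataset(x)
  m <- train_esom(ds, rows = 4, cols = 5, epochs = 10, seed = 2)
  bm <- best_matching_units(m, ds)
  expect_lt(max(bm$distance), 1e-6) # quantization error ~ 0
  m2 <- train_esom(ds, rows = 4, cols = 5, epochs = 10, seed = 2)
  expect_identical(m$weights, m2$weights)
  expect_error(train_esom(ds, rows = 1, cols = 5), class = "lipidmoe_spec_error")
})

test_that("BMUs equal a brute-force distance scan with row-major tie rule", {
  set.seed(11)
  sim <- matrix_dataset(matrix(rnorm(30 * 6), 30, 6))
  m <- train_esom(sim, rows = 6, cols = 8, epochs = 5, seed = 4)
  queries <- matrix_dataset(matrix(rnorm(50 * 6), 50, 6))
  colnames(queries$values) <- colnames(sim$values)
  bm <- best_matching_units(m, queries)
  for (i in seq_len(50)) {
    d2 <- apply(m$weights, 1L, function(w) sum((w - queries$values[i, ])^2))
    expect_identical(bm$neuron[i], which.min(d2)) # which.min = lowest index
  }
  # a sample equal to a neuron's weights maps there with distance 0
  q1 <- matrix_dataset(m$weights[17, , drop = FALSE])
  colnames(q1$values) <- colnames(sim$values)
  b1 <- best_matching_units(m, q1)
  expect_identical(b1$neuron, 17L)
  expect_equal(b1$distance, 0)

  bad <- matrix_dataset(matrix(rnorm(10), 5, 2))
  expect_error(best_matching_units(m, bad), class = "lipidmoe_shape_error")
})

test_that("U-matrix heights equal brute-force neighbor averages", {
  # identical weights -> all heights zero
  x <- matrix_dataset(matrix(1, 10, 2))
  m <- list(weights = matrix(1, 12, 2), rows = 3L, cols = 4L,
            feature_names = c("f001", "f002"))
  class(m) <- "esom_model"
  expect_equal(umatrix(m)$heights, rep(0, 12))

  # 3x3 torus, single unit spike: spiked neuron height 1, others 1/8
  spike <- matrix(0, 9, 1); spike[5, 1] <- 1
  m2 <- structure(list(weights = spike, rows = 3L, cols = 3L,
                       feature_names = "f1"), class = "esom_model")
  h <- umatrix(m2)$heights
  expect_equal(h[5], 1)
  expect_equal(h[-5], rep(1 / 8, 8))

  # random weights vs neighbor-enumeration oracle
  set.seed(9)
  w <- matrix(rnorm(20 * 3), 20, 3)
  m3 <- structure(list(weights = w, rows = 4L, cols = 5L,
                       feature_names = paste0("f", 1:3)),
                  class = "esom_model")
  h3 <- umatrix(m3)$heights
  nb <- lipidmoe:::toroidal_neighbors(4, 5)
  for (i in seq_len(20)) {
    expected <- mean(vapply(nb[[i]], function(j) sqrt(sum((w[j, ] - w[i, ])^2)),
                            numeric(1)))
    expect_equal(h3[i], expected, tolerance = 1e-12)
  }
})

test_that("two separated blobs yield two clusters matching blob identity", {
  set.seed(14)
  n <- 25
  x <- rbind(matrix(rnorm(n * 6, 0), n), matrix(rnorm(n * 6, 6), n))
  ds <- matrix_dataset(x)
  m <- train_esom(ds, rows = 10, cols = 15, epochs = 20, seed = 3)
  bm <- best_matching_units(m, ds)
  um <- umatrix(m)
  cl <- extract_clusters(um, bm, n_clusters = 2)
  truth <- rep(1:2, each = n)
  agreement <- max(mean(cl$cluster == truth), mean(cl$cluster == 3 - truth))
  expect_gte(agreement, 0.9)

  # flat field -> clustering failure; n_clusters = 1 -> trivial clustering
  flat <- structure(list(heights = rep(0, 150), rows = 10L, cols = 15L),
                    class = "lipid_umatrix")
  expect_error(extract_clusters(flat, bm, 2),
               class = "lipidmoe_clustering_failure")
  one <- extract_clusters(um, bm, n_clusters = 1)
  expect_identical(unique(one$cluster), 1L)
})

test_that("cluster-class association reproduces Fisher results on 2x2 designs", {
  mk_lab <- function(labels, ids) {
    structure(tibble::tibble(sample_id = ids, subject_id = ids,
                             label = factor(labels)),
              task = "timepoint", class = c("class_labeling", "tbl_df",
                                            "tbl", "data.frame"))
  }
  ids <- paste0("s", 1:20)
  perfect <- tibble::tibble(sample_id = ids, cluster = rep(1:2, each = 10))
  lab <- mk_lab(rep(c("day1", "day2"), each = 10), ids)
  res <- cluster_class_association(perfect, lab)
  expect_lt(res$p_value, 0.001)
  expect_identical(res$ci_high, Inf)

  null_cl <- tibble::tibble(sample_id = ids, cluster = rep(1:2, times = 10))
  lab2 <- mk_lab(rep(c("day1", "day2"), each = 10), ids)
  res2 <- cluster_class_association(null_cl, lab2) # balanced [[5,5],[5,5]]
  expect_equal(res2$p_value, 1)
  expect_equal(res2$odds_ratio, 1, tolerance = 1e-6)

  three <- tibble::tibble(sample_id = ids, cluster = rep(1:4, each = 5))
  expect_error(cluster_class_association(three, lab),
               class = "lipidmoe_contract_error")
})
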