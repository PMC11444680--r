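test_that("Kruskal-Wallis matches the defining rank formula, with and without ties", {
  # identical groups -> H = 0, p = 1
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # hand-computed H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 27/7
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)

  # tie-corrected H equals the oracle on small tied configurations
  set.seed(61)
  for (i in 1:25) {
    g1 <- sample(1:4, sample(2:4, 1), replace = TRUE)
    g2 <- sample(1:4, sample(2:4, 1), replace = TRUE)
    groups <- list(g1, g2)
    expect_equal(kruskal_wallis(groups)$statistic,
                 oracle_kruskal_h(groups), tolerance = 1e-10)
  }

  # invariance under strictly monotone transforms of the pooled data
  g <- list(rexp(5), rexp(6) + 0.5)
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, log))$statistic, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(numeric(0), 1:3)),
               class = "lipidmoe_input_error")
})

test_that("BH adjustment reproduces the step-up hand calculation", {
  expect_equal(adjust_p(0.03), 0.03)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_p(rep(1, 5)), rep(1, 5))
  set.seed(71)
  p <- runif(50)
  expect_equal(adjust_p(p), oracle_bh(p))
  expect_true(all(adjust_p(p) >= p))
  # order of distinct p-values is preserved
  dp <- c(0.001, 0.5, 0.04)
  expect_identical(order(adjust_p(dp)), order(dp))
  # Holm as the alternative correction
  expect_equal(adjust_p(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_error(adjust_p(c(0.5, 1.2)), class = "lipidmoe_domain_error")
})

test_that("Fisher's exact test matches the enumeration oracles", {
  null_tab <- matrix(c(5, 5, 5, 5), 2)
  res <- fisher_exact(null_tab)
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)

  # perfectly aligned table: p = 2 / choose(20, 10), OR infinite
  diag_tab <- matrix(c(10, 0, 0, 10), 2)
  res2 <- fisher_exact(diag_tab)
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res2$odds_ratio, Inf)
  expect_gt(res2$ci_low, 0)
  expect_identical(res2$ci_high, Inf)

  # worked mid-size table against all three oracles
  tab <- matrix(c(20, 9, 8, 19), 2) # [[20, 8], [9, 19]]
  res3 <- fisher_exact(tab)
  expect_equal(res3$p_value, oracle_fisher_p(tab), tolerance = 1e-10)
  expect_equal(res3$odds_ratio, oracle_fisher_or(tab), tolerance = 1e-4)
  ci <- oracle_fisher_ci(tab)
  expect_equal(res3$ci_low, ci[1], tolerance = 1e-4)
  expect_equal(res3$ci_high, ci[2], tolerance = 1e-4)

  # invariance under transposition and row/column swaps (p only)
  expect_equal(fisher_exact(t(tab))$p_value, res3$p_value, tolerance = 1e-12)
  expect_equal(fisher_exact(tab[2:1, ])$p_value, res3$p_value,
               tolerance = 1e-12)
  expect_equal(fisher_exact(tab[, 2:1])$p_value, res3$p_value,
               tolerance = 1e-12)

  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "lipidmoe_degenerate_table_error")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)),
               class = "lipidmoe_domain_error")
})

test_that("class enrichment builds the right table and flags unannotated input", {
  background <- tibble::tibble(
    feature_name = sprintf("f%03d", 1:255),
    feature_class = c(rep("sphingolipid", 46), rep("other", 209)))
  selected <- c(sprintf("f%03d", 1:11),       # 11 sphingolipids
                sprintf("f%03d", 100:115))    # 16 others
  res <- class_enrichment(selected, background, "sphingolipid")
  tab <- attr(res, "table")
  expect_identical(unname(tab["selected", "in_class"]), 11L)
  expect_identical(unname(tab["selected", "out_class"]), 16L)
  expect_identical(unname(tab["not_selected", "in_class"]), 35L)
  expect_identical(unname(tab["not_selected", "out_class"]), 193L)
  # oracle agreement on this configuration
  m <- matrix(c(11, 16, 35, 193), 2, byrow = TRUE)
  expect_equal(res$p_value, oracle_fisher_p(m), tolerance = 1e-10)
  expect_equal(res$odds_ratio, oracle_fisher_or(m), tolerance = 1e-4)

  # selecting every in-class feature and nothing else: extreme table
  all_in <- background$feature_name[1:46]
  res_ex <- class_enrichment(all_in, background, "sphingolipid")
  expect_lt(res_ex$p_value, 1e-20)

  expect_error(class_enrichment(c("f001", "zzz"), background, "sphingolipid"),
               class = "lipidmoe_annotation_error")
})

test_that("random selections give approximately uniform enrichment p-values", {
  background <- tibble::tibble(
    feature_name = sprintf("f%03d", 1:80),
    feature_class = c(rep("sphingolipid", 20), rep("other", 60)))
  set.seed(81)
  pvals <- replicate(300, {
    sel <- sample(background$feature_name, 15)
    class_enrichment(sel, background, "sphingolipid")$p_value
  })
  # discreteness makes exact uniformity unattainable; the distribution must
  # not be systematically anticonservative
  expect_gt(mean(pvals < 0.05), 0.0)
  expect_lt(mean(pvals < 0.05), 0.08)
  expect_gt(median(pvals), 0.3)
})

test_that("the marker screen orders and adjusts per-feature comparisons", {
  sim <- generate_lipidomics(small_spec(seed = 51L, effect_size_time = 2))
  ds <- apply_power(sim$dataset, 0)
  lab <- make_labeling(ds, "timepoint")
  screen <- marker_group_tests(ds, lab)
  expect_identical(nrow(screen), 40L)
  expect_true(all(screen$p_adjusted >= screen$p_value))
  # informative features dominate the top of the screen
  top5 <- screen$feature[1:5]
  expect_gte(length(intersect(top5, sim$truth$time)), 3L)
})
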