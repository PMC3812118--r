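# Edge statistics: pairwise r^2, rewiring permutation test, edge
# classification, trend/class tests and the tissue control.

test_that("pairwise r^2 hits exact and degenerate cases", {
  set.seed(1)
  a <- rnorm(36, 10)
  vals <- rbind(a, 2 * a + 1, rep(3, 36))
  expr <- make_expr(vals, n_dams = 6, n_sires = 6,
                    genes = c("gA", "gB", "gC"))
  expect_equal(pairwise_r2(expr, "gA", "gB", 1), 1)
  expect_true(is.na(pairwise_r2(expr, "gA", "gC", 1)))
  expect_error(pairwise_r2(expr, "gA", "missing", 1), "absent")
})

test_that("null r^2 between unstructured genes averages about 1/(n-1)", {
  set.seed(2)
  r2s <- replicate(300, {
    expr <- make_expr(matrix(rnorm(72), nrow = 2), n_dams = 6, n_sires = 6,
                      genes = c("x", "y"))
    pairwise_r2(expr, "x", "y", 1)
  })
  expect_lt(abs(mean(r2s) - 1 / 35), 0.01)
})

test_that("edge classification is calibrated and powered", {
  # pure-noise target: type-I rate at alpha = 0.01
  set.seed(3)
  labels <- replicate(400, {
    expr <- make_expr(rbind(ncii_family_values(), rnorm(36)),
                      n_dams = 6, n_sires = 6, genes = c("src", "tgt"))
    classify_edge(expr, "src", "tgt", 1)$label
  })
  expect_lt(mean(labels == "sensitive"), 0.04)
  # saturated upstream: all families far beyond K -> insensitive
  set.seed(4)
  sat <- replicate(40, {
    x <- runif(36, 8, 12)           # >> K = 1
    y <- edge_response("saturating", list(a = 0, v_max = 5, K = 1, h = 4),
                       x) + rnorm(36, 0, 0.05)
    expr <- make_expr(rbind(x, y), n_dams = 6, n_sires = 6,
                      genes = c("src", "tgt"))
    classify_edge(expr, "src", "tgt", 1)$label
  })
  expect_gte(mean(sat == "insensitive"), 0.95)
  # unclassifiable cases
  expr <- make_expr(rbind(rnorm(4), rnorm(4)), n_dams = 2, n_sires = 2,
                    genes = c("src", "tgt"))
  expect_true(is.na(classify_edge(expr, "src", "tgt", 1)$label))
})

test_that("sensitivity trend test matches the closed-form 2x2 chi-square", {
  cls <- tibble::tibble(
    timepoint = rep(1:2, each = 20),
    label = c(rep("sensitive", 18), rep("insensitive", 2),
              rep("sensitive", 2), rep("insensitive", 18)))
  res <- sensitivity_trend_test(cls)
  expect_equal(unname(res$statistic), 25.6)
  expect_lt(res$p_value, 1e-6)
  balanced <- tibble::tibble(timepoint = rep(1:2, each = 20),
                             label = rep(c("sensitive", "insensitive"), 20))
  res_b <- sensitivity_trend_test(balanced)
  expect_equal(unname(res_b$statistic), 0)
  expect_equal(res_b$p_value, 1)
  expect_error(sensitivity_trend_test(cls[cls$timepoint == 1, ]),
               ">= 2 time points")
})

test_that("interactor-vs-random test: positive control, null behaviour and
           the add-one correction", {
  # strong linear propagation -> small p
  ds <- simulate_cross(sim_config_morpho(seed = 31))
  set.seed(1)
  res <- interactor_vs_random_test(ds$expression, ds$network, 3,
                                   n_perm = 300)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$observed, quantile(res$null_stats, 0.95))
  expect_length(res$random_ci, 2)
  # severed edges (strength zero at all times) -> p not extreme
  cfg <- sim_config_morpho(seed = 32)
  cfg$edge_strength_by_time <- rep(0, 6)
  ds0 <- simulate_cross(cfg)
  set.seed(2)
  res0 <- interactor_vs_random_test(ds0$expression, ds0$network, 3,
                                    n_perm = 300)
  expect_gt(res0$p_value, 0.01)
  # n_perm = 1 can only give 1/2 or 1
  set.seed(3)
  res1 <- interactor_vs_random_test(ds$expression, ds$network, 3, n_perm = 1)
  expect_true(res1$p_value %in% c(0.5, 1))
  # permutation p-values are never zero
  expect_gt(res$p_value, 0)
  # uniform rewiring mode agrees qualitatively
  set.seed(4)
  res_u <- interactor_vs_random_test(ds$expression, ds$network, 3,
                                     n_perm = 300, mode = "uniform")
  expect_lt(res_u$p_value, 0.01)
})

test_that("rewiring keeps edge count and avoids known-interacting pairs", {
  ds <- simulate_cross(sim_config_morpho(seed = 33))
  net <- ds$network
  act <- active_genes(net, 3, ds$expression)
  nonint <- noninteracting_pairs(net, 3, ds$expression)
  linked <- unique(grnvar:::pair_key(net$edges$source, net$edges$target))
  set.seed(5)
  for (mode in c("degree", "uniform")) {
    pr <- grnvar:::rewire_edges(net$edges$source[1:4], net$edges$target[1:4],
                                act, linked, nonint, mode)
    expect_equal(nrow(pr), 4)
    keys <- grnvar:::pair_key(pr[, 1], pr[, 2])
    expect_false(any(keys %in% linked))
    expect_false(any(pr[, 1] == pr[, 2]))
  }
})

test_that("paternal-by-class test distinguishes shifted distributions", {
  set.seed(6)
  n <- 50
  cls <- tibble::tibble(
    source = sprintf("g%03d", 1:(2 * n)), target = "t", timepoint = 1,
    label = rep(c("sensitive", "insensitive"), each = n))
  comp <- tibble::tibble(gene = cls$source, timepoint = 1, term = "sire",
                         mean = c(rgamma(n, 9, 9 / 0.016),
                                  rgamma(n, 9, 9 / 0.029)),
                         scaled_mean = mean)
  fit <- fake_fit(components = comp)
  res <- paternal_by_class_test(fit, cls)
  expect_lt(res$ks$p_value, 0.05)
  expect_gt(res$by_class$mean_paternal[res$by_class$label == "insensitive"],
            res$by_class$mean_paternal[res$by_class$label == "sensitive"])
  expect_lt(res$time_adjusted_p, 0.05)
  # one empty class is an error
  expect_error(paternal_by_class_test(fit, cls[cls$label == "sensitive", ]),
               "non-empty")
})

test_that("tissue-composition control skips singleton tissues and flags a
           shared-factor tissue", {
  set.seed(7)
  z <- rnorm(36)
  vals <- rbind(z + rnorm(36, 0, 0.4), z + rnorm(36, 0, 0.4),
                z + rnorm(36, 0, 0.4),
                matrix(rnorm(36 * 4), nrow = 4),
                rep(0, 36))   # g8 never above background -> inactive
  expr <- make_expr(vals, n_dams = 6, n_sires = 6,
                    genes = sprintf("g%d", 1:8))
  edges <- tibble::tibble(
    source = c("g1", "g3", "g4", "g6", "g8"),
    target = c("g2", "g2", "g5", "g7", "g6"),
    sign = "activating",
    timepoints = list(1L, 1L, 1L, 1L, 1L),
    tissue = c("P", "P", "EM", "EM", "solo"))
  net <- network(edges)
  set.seed(8)
  # the 'solo' tissue keeps a single active gene (g8 fails the filter)
  expect_message(
    res <- tissue_composition_test(expr, net, 1, n_perm = 300,
                                   min_samples = 5),
    "skipped")
  p_shared <- res$p_value[res$tissue == "P"]
  expect_lt(p_shared, 0.05)
  expect_true(is.na(res$p_value[res$tissue == "solo"]))
})

test_that("repressing edges can be excluded without changing conclusions", {
  set.seed(9)
  x <- rnorm(36, 10)
  vals <- rbind(x, 2 * x + rnorm(36, 0, 0.5), 20 - x + rnorm(36, 0, 0.5))
  expr <- make_expr(vals, n_dams = 6, n_sires = 6,
                    genes = c("reg", "up_t", "down_t"))
  net <- network(tibble::tibble(
    source = c("reg", "reg"), target = c("up_t", "down_t"),
    sign = c("activating", "repressing"),
    timepoints = list(1L, 1L), tissue = "EM"))
  with_rep <- classify_edges(expr, net, timepoints = 1, min_samples = 5)
  without <- classify_edges(expr, net, timepoints = 1, min_samples = 5,
                            include_repressing = FALSE)
  expect_equal(nrow(with_rep), 2)
  expect_equal(nrow(without), 1)
  expect_false("down_t" %in% without$target)
  # the repressing edge is sensitive with a negative slope; the activating
  # edge keeps its label either way
  expect_equal(with_rep$label, c("sensitive", "sensitive"))
  expect_lt(with_rep$slope[with_rep$target == "down_t"], 0)
  expect_identical(with_rep$label[with_rep$target == "up_t"],
                   without$label)
})
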