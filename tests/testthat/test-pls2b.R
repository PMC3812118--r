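# Two-block PLS: SVD oracle agreement, RV identities, permutation
# behaviour, contribution scores and selection/enrichment helpers.

test_that("RV coefficient: self-congruence, rotation invariance, scaling", {
  set.seed(1)
  X <- matrix(rnorm(36 * 5), 36)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-10)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(rv_coefficient(X, X %*% Q), 1, tolerance = 1e-10)
  expect_equal(rv_coefficient(X, 3.7 * X %*% Q), 1, tolerance = 1e-10)
  Y <- matrix(rnorm(36 * 4), 36)
  expect_equal(rv_coefficient(3 * X, Y), rv_coefficient(X, 0.2 * Y),
               tolerance = 1e-12)
  expect_error(rv_coefficient(matrix(1, 10, 2), Y[1:10, ]), "zero total")
})

test_that("first PLS pair matches a grid-search maximizer on 2-column
           blocks", {
  set.seed(2)
  X <- scale(matrix(rnorm(40 * 2), 40), scale = FALSE)
  Y <- scale(cbind(X %*% c(0.8, -0.3) + rnorm(40, 0, 0.5),
                   rnorm(40)), scale = FALSE)
  fit <- fit_2bpls(X, Y, scale_x = FALSE, scale_y = FALSE)
  C <- crossprod(X, Y) / (nrow(X) - 1)
  angles <- seq(0, 2 * pi, length.out = 40000)
  # for each unit u the maximizing unit v is C'u / |C'u|; the objective
  # is then |C'u|
  obj <- vapply(angles, function(a) {
    sqrt(sum((t(C) %*% c(cos(a), sin(a)))^2))
  }, numeric(1))
  u_star <- c(cos(angles[which.max(obj)]), sin(angles[which.max(obj)]))
  u_fit <- fit$x_loadings[, 1]
  ang_err <- acos(pmin(1, abs(sum(u_star * u_fit))))
  expect_lt(ang_err, 1e-3)
  expect_equal(max(obj), fit$singular_values[1], tolerance = 1e-4)
})

test_that("factor-pair count is capped by the smaller block", {
  set.seed(3)
  X <- matrix(rnorm(30 * 12), 30)
  colnames(X) <- paste0("g", 1:12, "@t1")
  Y <- matrix(rnorm(30 * 6), 30)
  colnames(Y) <- paste0("rod", 1:6)
  fit <- fit_2bpls(X, Y)
  expect_lte(length(fit$singular_values), 6)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  # loading columns are unit norm
  expect_equal(unname(colSums(fit$x_loadings^2)),
               rep(1, ncol(fit$x_loadings)))
  # Frobenius identity: sum of squared singular values = total squared
  # cross-covariance
  C <- crossprod(scale(X), scale(Y, scale = FALSE)) / (nrow(X) - 1)
  expect_equal(sum(fit$singular_values^2), sum(C^2), tolerance = 1e-8)
})

test_that("a single shared column dominates the first pair", {
  set.seed(4)
  shared <- rnorm(50)
  X <- cbind(shared, matrix(rnorm(50 * 3, sd = 0.01), 50))
  colnames(X) <- paste0("g", 1:4, "@t1")
  Y <- cbind(shared, matrix(rnorm(50 * 2, sd = 0.01), 50))
  colnames(Y) <- c("a", "b", "c")
  fit <- fit_2bpls(X, Y, scale_x = FALSE, scale_y = FALSE)
  expect_equal(unname(abs(fit$x_loadings["g1@t1", 1])), 1, tolerance = 1e-3)
  expect_equal(unname(abs(fit$y_loadings["a", 1])), 1, tolerance = 1e-3)
  expect_equal(fit$singular_values[1], var(shared), tolerance = 0.01)
})

test_that("RV permutation test: positive control, boundary, never zero", {
  set.seed(5)
  Z <- matrix(rnorm(36 * 3), 36)
  X <- cbind(Z, matrix(rnorm(36 * 4), 36))
  Y <- cbind(Z %*% matrix(rnorm(9), 3), matrix(rnorm(36 * 2), 36))
  res <- rv_permutation_test(X, Y, n_perm = 300)
  expect_lte(res$p_value, 0.01)
  res1 <- suppressWarnings(rv_permutation_test(X, Y, n_perm = 1))
  expect_true(res1$p_value %in% c(0.5, 1))
  expect_warning(rv_permutation_test(X, Y, n_perm = 50), "n_perm")
})

test_that("weighted contributions and top-fraction selection", {
  set.seed(6)
  X <- matrix(rnorm(40 * 5), 40)
  colnames(X) <- paste0("g", 1:5, "@t1")
  Y <- matrix(rnorm(40 * 3), 40)
  colnames(Y) <- paste0("rod", 1:3)
  fit <- fit_2bpls(X, Y)
  wc <- weighted_contributions(fit)
  # bounded by the largest absolute loading (convexity of the weights)
  expect_true(all(wc$score <= apply(abs(fit$x_loadings), 1, max)[wc$measure]
                  + 1e-12))
  # single-factor result: score equals |loading| exactly
  one <- fit
  one$x_loadings <- fit$x_loadings[, 1, drop = FALSE]
  one$weights <- 1
  wc1 <- weighted_contributions(one)
  expect_equal(wc1$score[order(wc1$measure)],
               unname(abs(fit$x_loadings[order(rownames(fit$x_loadings)), 1])))
  # top-fraction counts
  scores <- tibble::tibble(measure = sprintf("m%03d@t%d", 1:220,
                                             rep(1:7, length.out = 220)),
                           score = runif(220))
  expect_length(top_fraction(scores, 0.05), 11)
  expect_length(top_fraction(scores, 0.10), 22)
  expect_equal(top_fraction(scores[1, ], 0.5), scores$measure[1])
  expect_error(top_fraction(scores[0, ], 0.1), "empty")
  # stable tie-break: equal scores keep original order
  tied <- tibble::tibble(measure = c("a@t1", "b@t1", "c@t1"),
                         score = c(1, 1, 1))
  expect_equal(top_fraction(tied, 0.3), "a@t1")
})

test_that("time-point enrichment matches the 2x2 chi-square", {
  universe <- sprintf("g%03d@t%d", 1:140, rep(1:7, each = 20))
  prop <- universe[seq(1, 140, by = 7)]   # spread across time points
  res <- timepoint_enrichment_test(prop, universe, timepoint = 1)
  expect_gt(res$p_value, 0.2)
  all_t1 <- universe[1:14]                # every selection from t1
  res2 <- timepoint_enrichment_test(all_t1, universe, timepoint = 1)
  expect_lt(res2$p_value, 1e-3)
  expect_equal(res2$df, 1)
  expect_error(timepoint_enrichment_test(character(0), universe), "empty")
})

test_that("tidy and glance methods expose the fit", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30); colnames(X) <- paste0("g", 1:4, "@t2")
  Y <- matrix(rnorm(30 * 3), 30); colnames(Y) <- paste0("r", 1:3)
  fit <- fit_2bpls(X, Y)
  td <- tidy(fit)
  expect_setequal(unique(td$block), c("expression", "skeletal"))
  expect_equal(nrow(td), (4 + 3) * length(fit$singular_values))
  gl <- glance(fit)
  expect_equal(gl$n_expression, 4)
  expect_true(gl$rv >= 0 && gl$rv <= 1)
})
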