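# NCII Gibbs model: agreement with the expected-mean-squares oracle,
# degenerate inputs, DIC comparisons, derived quantities and the
# cross-gene tests.

test_that("Gibbs posterior means track the method-of-moments oracle", {
  ds <- simulate_cross(sim_config_recovery(n_genes = 1, seed = 5))
  dat <- dplyr::filter(ds$expression, gene == "G001")
  set.seed(1)
  fit <- fit_ncii_gibbs(dat)
  mom <- ncii_moments(dat)
  for (tm in c("dam", "sire", "residual")) {
    gibbs <- fit$summary$mean[fit$summary$term == tm]
    oracle <- max(mom$estimate[mom$term == tm], 0)
    expect_lt(abs(gibbs - oracle), 0.05)
  }
  # credible intervals are positive and asymmetric around the mean
  expect_true(all(fit$summary$lower90 > 0))
  expect_true(all(fit$summary$upper90 - fit$summary$mean !=
                  fit$summary$mean - fit$summary$lower90))
  # scaled summaries are the raw summaries over the squared mean, exactly
  expect_equal(fit$summary$scaled_mean,
               fit$summary$mean / fit$gene_mean^2)
})

test_that("a constant response collapses all variance terms", {
  dat <- data.frame(value = rep(5, 72),
                    dam_id = rep(sprintf("D%d", 1:6), 12),
                    sire_id = rep(rep(sprintf("S%d", 1:6), each = 6), 2))
  set.seed(2)
  fit <- fit_ncii_gibbs(dat)
  # with nothing to explain, every variance falls to the lower (prior)
  # tail: scaled values at or below the prior CV^2 of 0.01
  expect_lt(max(fit$summary$scaled_mean), 0.02)
  expect_lt(fit$summary$mean[fit$summary$term == "residual"], 0.05)
  expect_lt(max(abs(fit$breeding_values$effect)), 0.1)
})

test_that("fewer than the sample floor is refused", {
  dat <- data.frame(value = rnorm(10), dam_id = rep(c("a", "b"), 5),
                    sire_id = rep(c("x", "y"), each = 5))
  expect_error(fit_ncii_gibbs(dat), "refusing")
})

test_that("a pure sire signal is attributed to the sire term", {
  hits <- vapply(1:20, function(i) {
    ds <- simulate_cross(sim_config_recovery(
      n_genes = 1, sigma2_dam = 0, sigma2_sire = 0.1, sigma2_inter = 0.005,
      sigma2_res = 0.05, seed = 100 + i))
    dat <- dplyr::filter(ds$expression, gene == "G001")
    set.seed(i)
    fit <- fit_ncii_gibbs(dat, chain = chain_control(iterations = 5000,
                                                     burnin = 1000))
    fit$summary$mean[fit$summary$term == "sire"] >
      fit$summary$mean[fit$summary$term == "dam"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("scaled and additive variance identities hold exactly", {
  expect_equal(scaled_variance(4, 2), 1)
  expect_equal(scaled_variance(0, 3), 0)
  k <- 7.3
  expect_equal(scaled_variance(k^2 * 4, k * 2), scaled_variance(4, 2))
  expect_error(scaled_variance(1, 0), "mean")
  expect_equal(additive_variance(sigma2_sire = 0.01,
                                 estimator = "four_x_sire"), 0.04)
  expect_equal(additive_variance(sigma2_dam = 0.01, sigma2_sire = 0.01,
                                 estimator = "two_x_sum"), 0.04)
  expect_equal(additive_variance(sigma2_dam = 0, sigma2_sire = 0,
                                 estimator = "two_x_sum"), 0)
})

test_that("DIC comparisons flag strong terms and ignore identical fits", {
  expect_false(dic_significance(100, 100)$significant)
  expect_equal(dic_significance(100, 100)$delta_dic, 0)
  expect_true(dic_significance(90, 100)$significant)
  # strong simulated sire effect: DIC should prefer the full model over
  # the no-sire model in most runs
  hits <- vapply(1:10, function(i) {
    ds <- simulate_cross(sim_config_recovery(
      n_genes = 1, sigma2_dam = 0.02, sigma2_sire = 0.2, sigma2_inter = 0.01,
      sigma2_res = 0.05, seed = 300 + i))
    dat <- dplyr::filter(ds$expression, gene == "G001")
    ch <- chain_control(iterations = 5000, burnin = 1000)
    set.seed(i); full <- fit_ncii_gibbs(dat, chain = ch)
    set.seed(i); red <- fit_ncii_gibbs(dat, chain = ch,
                                       terms = c("dam", "inter"))
    dic_significance(full$dic, red$dic)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("maternal vs paternal contrast behaves at the extremes", {
  comp <- fake_components(dam = rep(0.02, 12), sire = rep(0.02, 12))
  fit <- fake_fit(components = comp)
  res <- maternal_vs_paternal_test(fit, 1)
  expect_equal(res$p_value, 1)
  # dam uniformly double sire across 50 genes
  set.seed(1)
  sire <- runif(50, 0.01, 0.05)
  fit2 <- fake_fit(components = fake_components(dam = 2 * sire, sire = sire))
  expect_lt(maternal_vs_paternal_test(fit2, 1)$p_value, 0.01)
  expect_error(maternal_vs_paternal_test(fake_fit(
    components = fake_components(dam = 1:3 / 10, sire = 1:3 / 10)), 1),
    "at least")
})

test_that("trend test needs two time points and detects early excess", {
  one_t <- fake_fit(components = fake_components(dam = runif(12),
                                                 sire = runif(12)))
  expect_error(parental_effect_trend_test(one_t), ">= 2 time points")
  set.seed(2)
  comp <- dplyr::bind_rows(lapply(1:4, function(t) {
    scale <- if (t <= 2) 0.2 else 0.05
    fake_components(dam = rgamma(50, 4, 4 / scale),
                    sire = rgamma(50, 4, 4 / scale), timepoint = t)
  }))
  res <- parental_effect_trend_test(fake_fit(components = comp))
  expect_lt(res$kruskal$p_value, 0.01)
  expect_gt(res$early_vs_late$mean_early, res$early_vs_late$mean_late)
})

test_that("dam-sire rank correlation hits the exact extremes", {
  set.seed(3)
  v <- sort(runif(12, 0.01, 0.1))
  same <- fake_fit(components = fake_components(dam = v, sire = v))
  expect_equal(parental_effect_correlation(same, 1)$rho, 1)
  rev_fit <- fake_fit(components = fake_components(dam = v, sire = rev(v)))
  expect_equal(parental_effect_correlation(rev_fit, 1)$rho, -1)
})

test_that("eigenvalue variance is zero for isotropic G and detects rank-1
           structure via permutation", {
  expect_equal(eigenvalue_variance(diag(5)), 0)
  expect_equal(eigenvalue_variance(3.7 * diag(8)), 0)
  # shared latent parent factor across genes -> structured G
  set.seed(4)
  parents <- sprintf("D%d", 1:6)
  z <- rnorm(6)
  bv <- purrr::map_dfr(sprintf("g%02d", 1:10), function(g) {
    tibble::tibble(gene = g, timepoint = 1, role = "dam",
                   parent_id = parents,
                   effect = runif(1, 0.8, 1.2) * z + rnorm(6, 0, 0.1))
  })
  fit <- fake_fit(breeding_values = bv)
  set.seed(5)
  res <- gmatrix_structure_test(fit, 1, n_perm = 300, roles = "dam")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$statistic, quantile(res$null_stats, 0.95))
  # independent genes -> no structure signal
  bv_ind <- dplyr::mutate(bv, effect = rnorm(nrow(bv)))
  set.seed(6)
  res_ind <- gmatrix_structure_test(fake_fit(breeding_values = bv_ind), 1,
                                    n_perm = 300, roles = "dam")
  expect_gt(res_ind$p_value, 0.01)
  expect_warning(gmatrix_structure_test(fit, 1, n_perm = 50, roles = "dam"),
                 "n_perm")
})

test_that("breeding values are centred within role", {
  ds <- simulate_cross(sim_config_recovery(n_genes = 1, seed = 7))
  set.seed(1)
  fit <- fit_ncii_gibbs(dplyr::filter(ds$expression, gene == "G001"))
  sums <- tapply(fit$breeding_values$effect, fit$breeding_values$role, sum)
  expect_true(all(abs(sums) < 1e-10))
})
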