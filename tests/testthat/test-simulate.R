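# Synthetic-data generator: dimensions, determinism, edge responses,
# propagation and the realized-truth oracle.

test_that("a 6x6x2 cross over 7 time points yields 504 samples", {
  genes <- tibble::tibble(gene = sprintf("G%02d", 1:10), layer = "early")
  vs <- tidyr::crossing(gene = genes$gene, timepoint = 1:7)
  vs <- dplyr::mutate(vs, mean = 1, sigma2_dam = 0.01, sigma2_sire = 0.01,
                      sigma2_inter = 0.01, sigma2_res = 0.01)
  ds <- simulate_cross(sim_config(genes = genes, variance_spec = vs,
                                  seed = 2))
  expect_equal(dplyr::n_distinct(ds$expression$sample_id), 6 * 6 * 2 * 7)
  expect_equal(nrow(ds$expression), 10 * 504)
})

test_that("identical seeds give bit-identical datasets", {
  a <- simulate_cross(sim_config_morpho(seed = 9))
  b <- simulate_cross(sim_config_morpho(seed = 9))
  expect_identical(a$expression, b$expression)
  expect_identical(a$morphology, b$morphology)
  c <- simulate_cross(sim_config_morpho(seed = 10))
  expect_false(identical(a$expression$value, c$expression$value))
})

test_that("edge responses follow the linear and Hill forms", {
  expect_equal(edge_response("linear", list(a = 0, b = 2), 3), 6)
  # deep plateau: x = 10 K with h = 4
  expect_equal(edge_response("saturating",
                             list(a = 0, v_max = 1, K = 1, h = 4), 10),
               1e4 / (1 + 1e4))
  # half-saturation identity
  expect_equal(edge_response("saturating",
                             list(a = 0.5, v_max = 2, K = 3, h = 2), 3),
               0.5 + 1)
  expect_error(edge_response("quadratic", list(), 1), "unknown edge kind")
})

test_that("zero variance collapses families and propagation exactly", {
  genes <- tibble::tibble(gene = c("up", "down"), layer = c("early", "terminal"))
  net <- network(tibble::tibble(source = "up", target = "down",
                                sign = "activating", timepoints = list(1:6),
                                tissue = "EM"))
  es <- tibble::tibble(source = "up", target = "down", kind = "linear",
                       a = 0, b = 2, v_max = 1, K = 1, h = 1, noise_sd = 0)
  vs <- tidyr::crossing(gene = genes$gene, timepoint = 1:2)
  vs <- dplyr::mutate(vs, mean = ifelse(gene == "up", 2, 5),
                      sigma2_dam = 0, sigma2_sire = 0, sigma2_inter = 0,
                      sigma2_res = 0)
  ds <- simulate_cross(sim_config(genes = genes, timepoints = 1:2,
                                  network = net, edge_spec = es,
                                  variance_spec = vs, seed = 1))
  by_gene <- split(ds$expression$value, ds$expression$gene)
  expect_true(all(by_gene$up == 2))
  # propagated contribution is centred at the upstream mean, so the
  # downstream stays exactly at its own mean when every family sits at mu
  expect_true(all(by_gene$down == 5))
})

test_that("linear propagation with no residual gives r^2 = 1", {
  genes <- tibble::tibble(gene = c("up", "down"), layer = c("early", "terminal"))
  net <- network(tibble::tibble(source = "up", target = "down",
                                sign = "activating", timepoints = list(1:6),
                                tissue = "EM"))
  es <- tibble::tibble(source = "up", target = "down", kind = "linear",
                       a = 0, b = 1.5, v_max = 1, K = 1, h = 1, noise_sd = 0)
  vs <- tidyr::crossing(gene = genes$gene, timepoint = 1)
  vs <- dplyr::mutate(vs, mean = 1,
                      sigma2_dam = ifelse(gene == "up", 0.05, 0),
                      sigma2_sire = ifelse(gene == "up", 0.05, 0),
                      sigma2_inter = ifelse(gene == "up", 0.01, 0),
                      sigma2_res = 0)
  ds <- simulate_cross(sim_config(genes = genes, timepoints = 1,
                                  network = net, edge_spec = es,
                                  variance_spec = vs, seed = 8))
  expect_equal(pairwise_r2(ds$expression, "up", "down", 1), 1)
})

test_that("cyclic wiring is rejected", {
  genes <- tibble::tibble(gene = c("a", "b"), layer = "early")
  net <- network(tibble::tibble(source = c("a", "b"), target = c("b", "a"),
                                sign = "activating",
                                timepoints = list(1L, 1L),
                                tissue = c("EM", "P")))
  vs <- tidyr::crossing(gene = genes$gene, timepoint = 1)
  vs <- dplyr::mutate(vs, mean = 1, sigma2_dam = 0, sigma2_sire = 0,
                      sigma2_inter = 0, sigma2_res = 0.1)
  es <- tibble::tibble(source = c("a", "b"), target = c("b", "a"),
                       kind = "linear", a = 0, b = 1, v_max = 1, K = 1,
                       h = 1, noise_sd = 0)
  expect_error(simulate_cross(sim_config(genes = genes, timepoints = 1,
                                         network = net, edge_spec = es,
                                         variance_spec = vs, seed = 1)),
               "cyclic")
})

test_that("realized truth matches the drawn effects", {
  ds <- simulate_cross(sim_config_recovery(n_genes = 2, seed = 3))
  tr <- realized_truth_summary(ds)$components
  # realized variance equals the sample variance of the per-gene draws
  d1 <- ds$truth$components$dam_effects[[1]]
  expect_equal(tr$realized_dam[1], var(d1))
  # zero-variance config realizes exactly zero
  z <- simulate_cross(sim_config_recovery(n_genes = 1, sigma2_dam = 0,
                                          sigma2_sire = 0, sigma2_inter = 0,
                                          sigma2_res = 0.1, seed = 3))
  tz <- realized_truth_summary(z)$components
  expect_equal(tz$realized_dam, 0)
  expect_equal(tz$realized_sire, 0)
})

test_that("realized parental variance approaches nominal for many sires", {
  ds <- simulate_cross(sim_config_recovery(n_genes = 1, n_sires = 60,
                                           sigma2_sire = 0.05, seed = 6))
  tr <- realized_truth_summary(ds)$components
  # sample variance of n normals: SE = sigma2 * sqrt(2 / (n - 1))
  se <- 0.05 * sqrt(2 / 59)
  expect_lt(abs(tr$realized_sire - 0.05), 2 * se)
})

test_that("the maternal latent factor structures time point 1 only", {
  ds <- simulate_cross(sim_config_morpho(seed = 5))
  loaded <- dplyr::filter(ds$truth$maternal_loading, loading > 0)$gene
  mean_cor <- function(t) {
    fm <- family_means(dplyr::filter(ds$expression, timepoint == t,
                                     gene %in% loaded))
    m <- tidyr::pivot_wider(fm, id_cols = c("dam_id", "sire_id"),
                            names_from = "gene", values_from = "value")
    C <- cor(as.matrix(m[, -(1:2)]))
    mean(C[upper.tri(C)])
  }
  # genes carrying the dam latent factor covary at t1 but not at t2
  expect_gt(mean_cor(1), mean_cor(2) + 0.1)
})

test_that("zero-noise morphology differences equal loading x driver difference", {
  cfg <- sim_config_morpho(seed = 12)
  cfg$morphology$noise_sd <- 0
  cfg$morphology$maternal <- NULL
  ds <- simulate_cross(cfg)
  fm <- family_means(dplyr::filter(ds$expression, gene == "T01",
                                   timepoint == 6))
  cm <- dplyr::summarise(dplyr::group_by(ds$morphology, culture_id),
                         body = mean(body), .groups = "drop")
  cm$dam_id <- sub("x.*", "", cm$culture_id)
  cm$sire_id <- sub("_r.*", "", sub(".*x", "", cm$culture_id))
  j <- dplyr::inner_join(cm, fm, by = c("dam_id", "sire_id"))
  f1 <- j[1, ]; f2 <- j[nrow(j), ]
  expect_equal(f1$body - f2$body,
               cfg$morphology$drivers$loading * (f1$value - f2$value))
})

test_that("parental draws are stable under added genes (named substreams)", {
  a <- simulate_cross(sim_config_recovery(n_genes = 2, seed = 13))
  b <- simulate_cross(sim_config_recovery(n_genes = 5, seed = 13))
  va <- dplyr::filter(a$expression, gene == "G001")$value
  vb <- dplyr::filter(b$expression, gene == "G001")$value
  expect_identical(va, vb)
})
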