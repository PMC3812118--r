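# Ready-made simulation configurations. `sim_config_urchin()` is the
# package's reference condition: a 74-gene, 6x6x2, 7-time-point cross whose
# generator settings emulate the study system (maternal latent factor at the
# first time point, edge propagation absent before zygotic transcription
# dominates, roughly one third of active edges quantitative early rising to
# two thirds late, terminal-gene + maternal drivers of rod-length
# morphology). The numerical choices are documented in the methods
# vignette; they are fixed study conditions, not tuning knobs.

#' Reference simulation preset (sea-urchin study design)
#'
#' 74 genes in three layers (24 early, 30 intermediate, 20 terminal), a
#' 6 dam x 6 sire cross with 2 replicate cultures and 7 time points.
#' Early->intermediate edges are active over time points 1-3 or 2-4 with one
#' fifth linear (quantitative) response kinds, which classifies to roughly
#' one third sensitive once the family-structure false-positive rate is
#' accounted for; intermediate->terminal edges are
#' active over 4-6 with two thirds linear. Edge propagation is severed at
#' time points 1-2 (`edge_strength_by_time = c(0, 0, 1, 1, 1, 1)`),
#' emulating the predominantly maternal origin of early transcripts. A
#' per-dam latent factor loads on every gene at time point 1 and on all
#' skeletal rods; one terminal gene drives the body rod.
#'
#' @param seed master seed.
#' @param mean_expression mean relative expression level of every gene
#'   (unitless, after reference normalisation).
#' @param cv_residual residual coefficient of variation (default 0.13,
#'   within the 10-15% range typical of among-family expression variation).
#' @return a [sim_config()].
#' @export
sim_config_urchin <- function(seed = 1, mean_expression = 1,
                             cv_residual = 0.13) {
  early <- sprintf("E%02d", 1:24)
  mid <- sprintf("M%02d", 1:30)
  term <- sprintf("T%02d", 1:20)
  genes <- tibble::tibble(
    gene = c(early, mid, term),
    layer = rep(c("early", "intermediate", "terminal"), c(24, 30, 20)))

  # early->intermediate: windows 1-3 (odd rows) or 2-4 (even rows), 1/5 linear
  em <- tibble::tibble(
    source = early[(seq_along(mid) - 1) %% 24 + 1],
    target = mid,
    sign = "activating",
    timepoints = lapply(seq_along(mid),
                        function(i) if (i %% 2 == 1) 1:3 else 2:4),
    tissue = rep(c("EM", "VE", "E"), length.out = length(mid)),
    kind = ifelse(seq_along(mid) %% 5 == 1, "linear", "saturating"))
  # intermediate->terminal: two regulators each, window 4-6, 2/3 linear
  mt <- tibble::tibble(
    source = c(mid[(seq_along(term) - 1) %% 30 + 1],
               mid[(seq_along(term) + 6) %% 30 + 1]),
    target = rep(term, 2),
    sign = "activating",
    timepoints = rep(list(4:6), 2 * length(term)),
    tissue = rep(c("P", "M"), each = length(term)),
    kind = ifelse(seq_len(2 * length(term)) %% 3 == 0,
                  "saturating", "linear"))
  edges <- dplyr::bind_rows(em, mt)
  net <- network(dplyr::select(edges, -"kind"), genes = genes$gene)
  edge_spec <- dplyr::mutate(
    dplyr::select(edges, "source", "target", "kind"),
    a = 0, b = 2,
    v_max = mean_expression, K = 0.3 * mean_expression, h = 4,
    noise_sd = 0)

  s2_res <- (cv_residual * mean_expression)^2
  # scaled parental variances chosen so the additive variance
  # 2 (dam + sire) / mean^2 is ~0.28 at t1-2 and ~0.06 later
  par_early <- 0.070 * mean_expression^2
  par_late <- 0.015 * mean_expression^2
  variance_spec <- tidyr::crossing(gene = genes$gene, timepoint = 1:7)
  variance_spec <- dplyr::mutate(variance_spec,
    mean = mean_expression,
    sigma2_dam = ifelse(.data$timepoint <= 2, par_early, par_late),
    sigma2_sire = ifelse(.data$timepoint <= 2, par_early, par_late),
    sigma2_inter = 0.002 * mean_expression^2,
    sigma2_res = s2_res)

  set.seed(substream_seed(seed, "preset_maternal_loading"))
  maternal_loading <- tibble::tibble(
    gene = genes$gene,
    loading = pmax(rnorm(nrow(genes), 0.35, 0.08), 0.05) * mean_expression)

  rods <- c(body = 350, postoral_l = 250, postoral_r = 250,
            anterolateral_l = 150, anterolateral_r = 150, transverse = 80)
  morphology <- list(
    rods = rods,
    drivers = tibble::tibble(gene = "T01", timepoint = 6, rod = "body",
                             loading = 40 / mean_expression),
    maternal = rods * 0.03,
    noise_sd = 12,
    n_individuals = 24)

  sim_config(genes = genes, network = net, edge_spec = edge_spec,
             variance_spec = variance_spec,
             maternal_loading = maternal_loading,
             edge_strength_by_time = c(0, 0, 1, 1, 1, 1),
             morphology = morphology, seed = seed)
}

#' Variance-component recovery preset
#'
#' Independent genes (no network, no maternal factor) at a single time
#' point, all sharing one set of NCII variance components — the standard
#' condition for checking that the Gibbs model recovers known dam/sire/
#' interaction/residual variances from a 6 x 6 x 2 cross.
#'
#' @param n_genes number of genes.
#' @param mean_expression common gene mean.
#' @param sigma2_dam,sigma2_sire,sigma2_inter,sigma2_res true components.
#' @param n_dams,n_sires,n_replicates cross dimensions.
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
sim_config_recovery <- function(n_genes = 20, mean_expression = 1,
                                sigma2_dam = 0.05, sigma2_sire = 0.05,
                                sigma2_inter = 0.02, sigma2_res = 0.10,
                                n_dams = 6, n_sires = 6, n_replicates = 2,
                                seed = 1) {
  genes <- tibble::tibble(gene = sprintf("G%03d", seq_len(n_genes)),
                          layer = "early")
  variance_spec <- tibble::tibble(
    gene = genes$gene, timepoint = 1, mean = mean_expression,
    sigma2_dam = sigma2_dam, sigma2_sire = sigma2_sire,
    sigma2_inter = sigma2_inter, sigma2_res = sigma2_res)
  sim_config(genes = genes, timepoints = 1,
             n_dams = n_dams, n_sires = n_sires, n_replicates = n_replicates,
             variance_spec = variance_spec, seed = seed)
}

#' Small morphology-driver preset
#'
#' A reduced cross (12 genes: 4 early with maternal loading, 4 intermediate,
#' 4 terminal) in which one terminal gene and the per-dam maternal factor
#' drive rod-length morphology. Used for replicated driver-recovery
#' simulations where the full reference preset would be needlessly slow.
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
sim_config_morpho <- function(seed = 1) {
  genes <- tibble::tibble(
    gene = c(sprintf("E%02d", 1:4), sprintf("M%02d", 1:4),
             sprintf("T%02d", 1:4)),
    layer = rep(c("early", "intermediate", "terminal"), each = 4))
  edges <- tibble::tibble(
    source = c(sprintf("E%02d", 1:4), sprintf("M%02d", 1:4)),
    target = c(sprintf("M%02d", 1:4), sprintf("T%02d", 1:4)),
    sign = "activating",
    timepoints = c(rep(list(1:3), 4), rep(list(4:6), 4)),
    tissue = "P")
  net <- network(edges, genes = genes$gene)
  edge_spec <- tibble::tibble(
    source = edges$source, target = edges$target,
    kind = "linear", a = 0, b = 2, v_max = 1, K = 0.3, h = 4, noise_sd = 0)
  variance_spec <- tidyr::crossing(gene = genes$gene, timepoint = 1:7)
  variance_spec <- dplyr::mutate(variance_spec,
    mean = 1,
    sigma2_dam = ifelse(.data$timepoint <= 2, 0.070, 0.015),
    sigma2_sire = ifelse(.data$timepoint <= 2, 0.070, 0.015),
    sigma2_inter = 0.002, sigma2_res = 0.018)
  # E01 is the maternal-latent-ONLY gene: its expression variation carries
  # no parental (genetic) component at all, only the dam latent factor
  # plus residual noise — the designated negative control for the
  # maternal-conditioned association test
  variance_spec <- dplyr::mutate(variance_spec,
    sigma2_dam = ifelse(.data$gene == "E01", 0, .data$sigma2_dam),
    sigma2_sire = ifelse(.data$gene == "E01", 0, .data$sigma2_sire),
    sigma2_inter = ifelse(.data$gene == "E01", 0, .data$sigma2_inter))
  maternal_loading <- tibble::tibble(gene = genes$gene,
                                     loading = c(rep(0.35, 4), rep(0, 8)))
  rods <- c(body = 350, postoral_l = 250, postoral_r = 250,
            anterolateral_l = 150, anterolateral_r = 150, transverse = 80)
  morphology <- list(
    rods = rods,
    drivers = tibble::tibble(gene = "T01", timepoint = 6, rod = "body",
                             loading = 70),
    maternal = rods * 0.03,
    noise_sd = 12,
    n_individuals = 24)
  sim_config(genes = genes, network = net, edge_spec = edge_spec,
             variance_spec = variance_spec,
             maternal_loading = maternal_loading,
             edge_strength_by_time = c(0, 0, 1, 1, 1, 1),
             morphology = morphology, seed = seed)
}
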