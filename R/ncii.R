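# NCII variance decomposition per gene x time: Bayesian hierarchical mixed
# model (Gibbs sampler in src/gibbs.cpp) with inverse-gamma priors on the
# dam, sire, dam-x-sire and residual variances, DIC-based term significance,
# posterior-mean breeding values, and a method-of-moments (expected mean
# squares) cross-check estimator.

#' Chain and prior settings for the NCII Gibbs sampler
#'
#' @param iterations total Gibbs iterations (default 13000).
#' @param burnin discarded initial iterations (default 3000).
#' @param thin keep every `thin`-th draw (default 10; 1000 kept draws).
#' @param prior_shape inverse-gamma shape for every variance term. The
#'   default 1.002 is diffuse; the scale is set per response so the prior
#'   mode equals `(prior_cv * mean(y))^2`.
#' @param prior_cv prior is centred at this coefficient of variation
#'   (default 0.1, i.e. 10% of the gene's mean expression).
#' @param ess_floor flag a chain as non-convergent when the effective sample
#'   size of any variance falls below this (default 100).
#' @return list of settings.
#' @export
chain_control <- function(iterations = 13000, burnin = 3000, thin = 10,
                          prior_shape = 1.002, prior_cv = 0.1,
                          ess_floor = 100) {
  stopifnot(iterations > burnin, thin >= 1, prior_shape > 0, prior_cv > 0)
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), prior_shape = prior_shape,
       prior_cv = prior_cv, ess_floor = ess_floor)
}

# effective sample size from the initial positive sequence of autocorrelations
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- as.numeric(stats::acf(x, plot = FALSE,
                               lag.max = min(200, n - 1))$acf)[-1]
  pos <- which(rho <= 0)
  if (length(pos) > 0) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

posterior_mode <- function(x) {
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Fit the NCII Gibbs model to one response
#'
#' Fits `y = mu + dam + sire + dam:sire + e` with zero-mean normal random
#' effects and diffuse inverse-gamma priors centred at
#' `(prior_cv * mean(y))^2`, by Gibbs sampling. Credible intervals are
#' posterior quantiles and therefore positive and asymmetric. The design
#' may be unbalanced; rows with missing response are dropped. Fewer than
#' `min_samples` usable samples is an error (too few observations to
#' estimate variances).
#'
#' @param data data frame with columns `value`, `dam_id`, `sire_id` (one
#'   row per sample; replicates are separate rows).
#' @param chain a [chain_control()].
#' @param terms character subset of `c("dam", "sire", "inter")` to include
#'   (the full model by default; drop one for nested DIC comparisons).
#' @param min_samples refusal threshold (default 20).
#' @return list: `summary` (tibble of posterior mean/mode/median/90% CI and
#'   scaled versions per term), `samples` (kept draws), `breeding_values`
#'   (centred posterior-mean dam and sire effects), `dic`, `pd`,
#'   `gene_mean`, `ess`, `converged`.
#' @export
fit_ncii_gibbs <- function(data, chain = chain_control(),
                           terms = c("dam", "sire", "inter"),
                           min_samples = 20) {
  ok <- !is.na(data$value)
  data <- data[ok, , drop = FALSE]
  n <- nrow(data)
  if (n < min_samples) {
    stop("refusing to fit: only ", n, " usable samples (need ",
         min_samples, ")", call. = FALSE)
  }
  y <- data$value
  dam_f <- factor(data$dam_id)
  sire_f <- factor(data$sire_id)
  inter_f <- factor(paste(data$dam_id, data$sire_id, sep = ":"))
  gene_mean <- mean(y)
  prior_mode <- (chain$prior_cv * abs(gene_mean))^2
  if (prior_mode == 0) prior_mode <- 1e-6
  prior_scale <- prior_mode * (chain$prior_shape + 1)

  res <- .gibbs_ncii_cpp(
    y, as.integer(dam_f) - 1L, as.integer(sire_f) - 1L,
    as.integer(inter_f) - 1L,
    nlevels(dam_f), nlevels(sire_f), nlevels(inter_f),
    "dam" %in% terms, "sire" %in% terms, "inter" %in% terms,
    chain$iterations, chain$burnin, chain$thin,
    chain$prior_shape, prior_scale)

  samples <- res$samples
  dbar <- mean(samples[, "deviance"])
  pd <- dbar - res$deviance_hat
  dic <- dbar + pd

  term_cols <- c(dam = "sigma2_dam", sire = "sigma2_sire",
                 inter = "sigma2_inter", residual = "sigma2_res")
  keep_terms <- c(intersect(c("dam", "sire", "inter"), terms), "residual")
  summ <- purrr::map_dfr(keep_terms, function(tm) {
    x <- samples[, term_cols[[tm]]]
    tibble::tibble(term = tm, mean = mean(x), mode = posterior_mode(x),
                   median = median(x),
                   lower90 = unname(quantile(x, 0.05)),
                   upper90 = unname(quantile(x, 0.95)),
                   ess = ess(x))
  })
  summ <- dplyr::mutate(summ,
    scaled_mean = scaled_variance(.data$mean, gene_mean),
    scaled_median = scaled_variance(.data$median, gene_mean))

  bv <- dplyr::bind_rows(
    if ("dam" %in% terms) tibble::tibble(
      role = "dam", parent_id = levels(dam_f),
      effect = res$dam_mean - mean(res$dam_mean)),
    if ("sire" %in% terms) tibble::tibble(
      role = "sire", parent_id = levels(sire_f),
      effect = res$sire_mean - mean(res$sire_mean)))

  list(summary = summ, samples = samples, breeding_values = bv,
       dic = dic, pd = pd, gene_mean = gene_mean, n = n,
       ess = min(summ$ess),
       converged = min(summ$ess) >= chain$ess_floor)
}

#' Fit NCII variance components across genes and time points
#'
#' Maps [fit_ncii_gibbs()] over every (gene, time point) of a long
#' expression tibble that passes [expressed_filter()], optionally adding
#' DIC comparisons against models dropping each parental term. Each fit
#' draws its chain from a named substream of `seed`, so results are
#' reproducible and independent of fit order.
#'
#' @param expr long expression tibble (see [read_expression()]).
#' @param genes,timepoints optional subsets (default: everything present).
#' @param chain a [chain_control()].
#' @param dic also fit the three reduced models and flag term significance
#'   by DIC (default TRUE; roughly quadruples runtime).
#' @param dic_threshold a term is significant when
#'   `DIC(full) < DIC(reduced) - dic_threshold` (default 2).
#' @param min_samples per-(gene, time) sample floor; combinations below it
#'   are skipped and listed in `skipped`.
#' @param seed master seed for all chains.
#' @return object of class `ncii_fit`: list with `components` (long tibble:
#'   gene, timepoint, term, posterior summaries, scaled versions),
#'   `gene_stats` (per gene x time: gene mean, n, DICs, significance flags,
#'   convergence), `breeding_values`, `skipped`, `chain`.
#' @export
fit_ncii <- function(expr, genes = NULL, timepoints = NULL,
                     chain = chain_control(), dic = TRUE, dic_threshold = 2,
                     min_samples = 20, seed = 1) {
  assert_expr_tbl(expr)
  genes <- genes %||% unique(expr$gene)
  timepoints <- timepoints %||% sort(unique(expr$timepoint))
  grid <- expand.grid(gene = genes, timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  comp <- list(); gs <- list(); bvs <- list(); skipped <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid$gene[i]; t <- grid$timepoint[i]
    if (!expressed_filter(expr, g, t, min_samples)) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(gene = g, timepoint = t,
                       reason = "fewer above-background samples than floor")
      next
    }
    dat <- dplyr::filter(expr, .data$gene == !!g, .data$timepoint == !!t)
    set.seed(substream_seed(seed, paste0("gibbs:", g, ":", t)))
    fit <- fit_ncii_gibbs(dat, chain = chain, min_samples = min_samples)
    comp[[length(comp) + 1]] <- dplyr::mutate(fit$summary, gene = g,
                                              timepoint = t, .before = 1)
    row <- tibble::tibble(gene = g, timepoint = t,
                          gene_mean = fit$gene_mean, n_samples = fit$n,
                          dic_full = fit$dic, converged = fit$converged)
    if (dic) {
      red <- purrr::map(c("dam", "sire", "inter"), function(drop_term) {
        set.seed(substream_seed(seed,
                                paste0("gibbs:", g, ":", t, ":no_", drop_term)))
        fit_ncii_gibbs(dat, chain = chain,
                       terms = setdiff(c("dam", "sire", "inter"), drop_term),
                       min_samples = min_samples)
      })
      row$dic_no_dam <- red[[1]]$dic
      row$dic_no_sire <- red[[2]]$dic
      row$dic_no_inter <- red[[3]]$dic
      row$female_sig <- dic_significance(fit$dic, red[[1]]$dic,
                                         dic_threshold)$significant
      row$male_sig <- dic_significance(fit$dic, red[[2]]$dic,
                                       dic_threshold)$significant
      row$interaction_sig <- dic_significance(fit$dic, red[[3]]$dic,
                                              dic_threshold)$significant
    }
    gs[[length(gs) + 1]] <- row
    bvs[[length(bvs) + 1]] <- dplyr::mutate(fit$breeding_values, gene = g,
                                            timepoint = t, .before = 1)
    if (!fit$converged) {
      warning("low effective sample size for ", g, " at t", t, call. = FALSE)
    }
  }
  structure(list(components = dplyr::bind_rows(comp),
                 gene_stats = dplyr::bind_rows(gs),
                 breeding_values = dplyr::bind_rows(bvs),
                 skipped = dplyr::bind_rows(skipped),
                 chain = chain, seed = seed),
            class = "ncii_fit")
}

#' @export
print.ncii_fit <- function(x, ...) {
  cat("<ncii_fit> ", dplyr::n_distinct(x$components$gene), " genes x ",
      dplyr::n_distinct(x$components$timepoint), " time points; ",
      nrow(x$skipped), " combinations skipped\n", sep = "")
  invisible(x)
}

#' Scale a variance by the squared gene mean
#'
#' `v / mean^2` is unitless; its square root is the coefficient of
#' variation, which makes variances comparable across genes expressed at
#' different levels. Invariant under rescaling of the measurement unit:
#' `scaled_variance(k^2 v, k m) == scaled_variance(v, m)`.
#'
#' @param v variance (>= 0).
#' @param mean gene mean (> 0).
#' @return scaled variance.
#' @export
scaled_variance <- function(v, mean) {
  if (any(mean <= 0)) stop("mean must be > 0", call. = FALSE)
  v / mean^2
}

#' Additive genetic variance from NCII components
#'
#' In a half-sib design the additive variance is four times a single
#' parental variance component, or twice the sum of both parental
#' components.
#'
#' @param sigma2_dam,sigma2_sire parental variance components.
#' @param estimator `"four_x_sire"`, `"four_x_dam"` or `"two_x_sum"`.
#' @return additive variance estimate.
#' @export
additive_variance <- function(sigma2_dam = NULL, sigma2_sire = NULL,
                              estimator = c("four_x_sire", "four_x_dam",
                                            "two_x_sum")) {
  estimator <- match.arg(estimator)
  switch(estimator,
         four_x_sire = 4 * sigma2_sire,
         four_x_dam = 4 * sigma2_dam,
         two_x_sum = 2 * (sigma2_dam + sigma2_sire))
}

#' DIC model comparison
#'
#' A dropped term is supported (significant) when the full model's DIC
#' undercuts the reduced model's by more than `threshold`.
#'
#' @param dic_full,dic_reduced DIC values of nested fits on the same data.
#' @param threshold required DIC improvement (default 2).
#' @return list with `significant` (logical) and `delta_dic`
#'   (`DIC(reduced) - DIC(full)`; positive favours the full model).
#' @export
dic_significance <- function(dic_full, dic_reduced, threshold = 2) {
  delta <- dic_reduced - dic_full
  list(significant = delta > threshold, delta_dic = delta)
}

#' Method-of-moments NCII variance components
#'
#' Expected-mean-squares estimator from the two-way random-effects ANOVA
#' `value ~ dam * sire`, the classical NCII analysis. Estimates can be
#' negative (they are not truncated); intended as an independent
#' cross-check of the Gibbs posterior means on near-balanced designs.
#'
#' @param data data frame with `value`, `dam_id`, `sire_id`.
#' @return tibble with `term` and `estimate` for dam, sire, inter, residual.
#' @export
ncii_moments <- function(data) {
  data <- data[!is.na(data$value), , drop = FALSE]
  dam_f <- factor(data$dam_id); sire_f <- factor(data$sire_id)
  n_dam <- nlevels(dam_f); n_sire <- nlevels(sire_f)
  r <- nrow(data) / (n_dam * n_sire)   # average replicates per cell
  fit <- aov(value ~ dam_f * sire_f, data = data.frame(
    value = data$value, dam_f = dam_f, sire_f = sire_f))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  ms_res <- ms[["Residuals"]]
  ms_int <- ms[["dam_f:sire_f"]]
  tibble::tibble(
    term = c("dam", "sire", "inter", "residual"),
    estimate = c((ms[["dam_f"]] - ms_int) / (r * n_sire),
                 (ms[["sire_f"]] - ms_int) / (r * n_dam),
                 (ms_int - ms_res) / r,
                 ms_res))
}
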