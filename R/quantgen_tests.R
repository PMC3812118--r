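# Cross-gene tests on fitted NCII components: maternal vs paternal
# contrasts, developmental trends, dam-sire magnitude correlation, and the
# G-matrix eigenvalue-variance structure statistic.

component_by_gene <- function(fit, timepoint, term, scaled = TRUE) {
  col <- if (scaled) "scaled_mean" else "mean"
  x <- dplyr::filter(fit$components, .data$timepoint == !!timepoint,
                     .data$term == !!term)
  setNames(x[[col]], x$gene)
}

#' Maternal versus paternal component test
#'
#' Paired Wilcoxon signed-rank test of the dam against the sire variance
#' component (scaled by the squared gene mean by default) across genes at
#' one time point. After the first time point dam and sire contributions
#' should be symmetric; a directional excess of the dam component signals
#' maternal (egg-quality / provisioning) influence, so the default
#' alternative is one-sided.
#'
#' @param fit an [fit_ncii()] object.
#' @param timepoint time point to test.
#' @param scaled use scaled components (default TRUE).
#' @param alternative passed to [wilcox.test()] (default `"greater"`:
#'   dam exceeds sire).
#' @param min_genes minimum genes with both components (default 10).
#' @return tibble: timepoint, n_genes, mean dam and sire components,
#'   `statistic`, `p_value`.
#' @export
maternal_vs_paternal_test <- function(fit, timepoint, scaled = TRUE,
                                      alternative = "greater",
                                      min_genes = 10) {
  dam <- component_by_gene(fit, timepoint, "dam", scaled)
  sire <- component_by_gene(fit, timepoint, "sire", scaled)
  genes <- intersect(names(dam), names(sire))
  if (length(genes) < min_genes) {
    stop("need at least ", min_genes, " genes with both components",
         call. = FALSE)
  }
  d <- dam[genes]; s <- sire[genes]
  if (all(d == s)) {
    return(tibble::tibble(timepoint = timepoint, n_genes = length(genes),
                          mean_dam = mean(d), mean_sire = mean(s),
                          statistic = NA_real_, p_value = 1))
  }
  wt <- suppressWarnings(wilcox.test(d, s, paired = TRUE,
                                     alternative = alternative))
  tibble::tibble(timepoint = timepoint, n_genes = length(genes),
                 mean_dam = mean(d), mean_sire = mean(s),
                 statistic = unname(wt$statistic), p_value = wt$p.value)
}

parental_measure <- function(fit, measure, scaled) {
  col <- if (scaled) "scaled_mean" else "mean"
  wide <- tidyr::pivot_wider(
    dplyr::select(fit$components, "gene", "timepoint", "term",
                  dplyr::all_of(col)),
    names_from = "term", values_from = dplyr::all_of(col))
  dplyr::mutate(wide, value = switch(measure,
    additive = 2 * (.data$dam + .data$sire),
    dam = .data$dam,
    sire = .data$sire))
}

#' Developmental trend in parental variance components
#'
#' Kruskal-Wallis rank test of the per-gene parental variance measure
#' across time-point groups, plus a Wilcoxon rank-sum comparison of the
#' early (default time points 1-2) against the later time points. The
#' measure defaults to the additive variance `2 (dam + sire)` on the
#' scaled components. Supplying a network restricts each gene to the time
#' points at which it is active (incident to an active edge).
#'
#' @param fit an [fit_ncii()] object.
#' @param measure `"additive"`, `"dam"` or `"sire"`.
#' @param scaled use scaled components (default TRUE).
#' @param early time points forming the early group (default `1:2`).
#' @param net optional [network()] restricting gene x time to active genes.
#' @return list: `kruskal` (tibble: statistic, df, p_value),
#'   `early_vs_late` (tibble: mean_early, mean_late, statistic, p_value),
#'   `data` (the gene x time measures used).
#' @export
parental_effect_trend_test <- function(fit, measure = "additive",
                                       scaled = TRUE, early = 1:2,
                                       net = NULL) {
  dat <- parental_measure(fit, measure, scaled)
  if (!is.null(net)) {
    keep <- vapply(seq_len(nrow(dat)), function(i) {
      t <- dat$timepoint[i]
      t >= 1 && t <= 6 && dat$gene[i] %in% active_genes(net, t)
    }, logical(1))
    dat <- dat[keep, , drop = FALSE]
  }
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  if (dplyr::n_distinct(dat$timepoint) < 2) {
    stop("need components at >= 2 time points", call. = FALSE)
  }
  kw <- kruskal.test(dat$value, factor(dat$timepoint))
  e <- dat$value[dat$timepoint %in% early]
  l <- dat$value[!dat$timepoint %in% early]
  evl <- if (length(e) > 0 && length(l) > 0) {
    wt <- suppressWarnings(wilcox.test(e, l))
    tibble::tibble(mean_early = mean(e), mean_late = mean(l),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  } else {
    tibble::tibble(mean_early = NA_real_, mean_late = NA_real_,
                   statistic = NA_real_, p_value = NA_real_)
  }
  list(kruskal = tibble::tibble(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p_value = kw$p.value),
       early_vs_late = evl, data = dat)
}

#' Correlation between dam and sire component magnitudes
#'
#' Spearman rank correlation across genes of the dam against the sire
#' scaled component at one time point. Predominantly zygotic transcription
#' makes the two parental contributions track each other; a weaker
#' correlation indicates an extra maternal channel.
#'
#' @inheritParams maternal_vs_paternal_test
#' @return tibble: timepoint, n_genes, `rho`, `p_value`.
#' @export
parental_effect_correlation <- function(fit, timepoint, scaled = TRUE,
                                        min_genes = 10) {
  dam <- component_by_gene(fit, timepoint, "dam", scaled)
  sire <- component_by_gene(fit, timepoint, "sire", scaled)
  genes <- intersect(names(dam), names(sire))
  if (length(genes) < min_genes) {
    stop("need at least ", min_genes, " genes", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(dam[genes], sire[genes],
                                  method = "spearman", exact = FALSE))
  tibble::tibble(timepoint = timepoint, n_genes = length(genes),
                 rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Variance of normalized eigenvalues
#'
#' Eigenvalues of a covariance matrix are normalized to proportions (sum
#' 1); their variance measures how concentrated the matrix is along few
#' directions — 0 for an identity-like (isotropic) matrix, large when one
#' axis dominates. Tiny negative eigenvalues from numerical error are
#' clipped to zero.
#'
#' @param G symmetric covariance matrix.
#' @return scalar >= 0.
#' @export
eigenvalue_variance <- function(G) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  if (sum(ev) == 0) return(0)
  var(ev / sum(ev))
}

#' G-matrix structure permutation test
#'
#' Estimates the genetic covariance matrix among genes at one time point
#' from parental breeding values (parents as observations, dam and sire
#' panels stacked after per-role centring), summarizes its structure by the
#' variance of the normalized eigenvalues, and compares it to a null in
#' which each gene's breeding values are permuted across parents
#' independently (within role) — destroying cross-gene covariance while
#' preserving each gene's margin.
#'
#' @param fit an [fit_ncii()] object.
#' @param timepoint time point.
#' @param n_perm permutations (default 1000; below 100 warns).
#' @param roles parental panels to stack (default dam and sire).
#' @return list of class `gmatrix_test`: `G`, `eigenvalues`, `statistic`,
#'   `null_stats`, `p_value`, `n_genes`, `timepoint`.
#' @export
gmatrix_structure_test <- function(fit, timepoint, n_perm = 1000,
                                   roles = c("dam", "sire")) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  bv <- dplyr::filter(fit$breeding_values, .data$timepoint == !!timepoint,
                      .data$role %in% roles)
  if (nrow(bv) == 0) stop("no breeding values at that time point",
                          call. = FALSE)
  wide <- tidyr::pivot_wider(bv, id_cols = c("role", "parent_id"),
                             names_from = "gene", values_from = "effect")
  X <- as.matrix(wide[, -(1:2)])
  if (ncol(X) < 3) stop("need breeding values for >= 3 genes", call. = FALSE)
  role_f <- wide$role
  for (r in unique(role_f)) {
    X[role_f == r, ] <- scale(X[role_f == r, , drop = FALSE],
                              center = TRUE, scale = FALSE)
  }
  G <- stats::cov(X)
  observed <- eigenvalue_variance(G)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    Xp <- X
    for (r in unique(role_f)) {
      rows <- which(role_f == r)
      for (j in seq_len(ncol(Xp))) {
        Xp[rows, j] <- Xp[sample(rows), j]
      }
    }
    eigenvalue_variance(stats::cov(Xp))
  }, numeric(1))
  structure(list(G = G,
                 eigenvalues = eigen(G, symmetric = TRUE,
                                     only.values = TRUE)$values,
                 statistic = observed, null_stats = null_stats,
                 p_value = perm_pvalue(null_stats, observed),
                 n_genes = ncol(X), timepoint = timepoint),
            class = "gmatrix_test")
}

#' @export
print.gmatrix_test <- function(x, ...) {
  cat("<gmatrix_test> t =", x$timepoint, ":", x$n_genes,
      "genes, eigenvalue variance =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 3), "\n")
  invisible(x)
}
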