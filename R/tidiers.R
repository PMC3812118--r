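# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy an NCII fit
#'
#' One row per gene x time x variance term with posterior summaries.
#'
#' @param x an [fit_ncii()] object.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.ncii_fit <- function(x, ...) x$components

#' Glance at an NCII fit
#' @param x an [fit_ncii()] object.
#' @param ... unused.
#' @return one-row tibble: fits, skips, convergence failures, chain size.
#' @export
glance.ncii_fit <- function(x, ...) {
  tibble::tibble(
    n_fits = nrow(x$gene_stats),
    n_skipped = nrow(x$skipped),
    n_nonconverged = sum(!x$gene_stats$converged),
    iterations = x$chain$iterations,
    kept_draws = (x$chain$iterations - x$chain$burnin) %/% x$chain$thin)
}

#' Tidy a two-block PLS fit
#'
#' Loadings in long form, one row per measure x factor per block.
#'
#' @param x a [fit_2bpls()] object.
#' @param ... unused.
#' @return tibble: block, measure, factor, loading, singular_value, weight.
#' @export
tidy.pls2b <- function(x, ...) {
  long <- function(L, block) {
    tibble::tibble(
      block = block,
      measure = rep(rownames(L), times = ncol(L)),
      factor = rep(seq_len(ncol(L)), each = nrow(L)),
      loading = as.numeric(L))
  }
  out <- dplyr::bind_rows(long(x$x_loadings, "expression"),
                          long(x$y_loadings, "skeletal"))
  out$singular_value <- x$singular_values[out$factor]
  out$weight <- x$weights[out$factor]
  out
}

#' Glance at a two-block PLS fit
#' @param x a [fit_2bpls()] object.
#' @param ... unused.
#' @return one-row tibble: rv, rv_p (if computed), factor count, block
#'   sizes, first-factor weight.
#' @export
glance.pls2b <- function(x, ...) {
  tibble::tibble(rv = x$rv, rv_p = x$rv_p %||% NA_real_,
                 n_factors = length(x$singular_values),
                 n_expression = nrow(x$x_loadings),
                 n_skeletal = nrow(x$y_loadings),
                 first_factor_weight = x$weights[1])
}

#' Tidy a skeletal PCA
#' @param x a [skeletal_pca()] object.
#' @param ... unused.
#' @return tibble: component, measure, loading, variance_fraction.
#' @export
tidy.skeletal_pca <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    component = rep(seq_len(ncol(L)), each = nrow(L)),
    measure = rep(rownames(L), times = ncol(L)),
    loading = as.numeric(L),
    variance_fraction = rep(x$variance_fraction, each = nrow(L)))
}

#' Glance at a skeletal PCA
#' @param x a [skeletal_pca()] object.
#' @param ... unused.
#' @return one-row tibble with culture count and leading variance
#'   fractions.
#' @export
glance.skeletal_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble::tibble(n_cultures = nrow(x$scores), n_measures = nrow(x$loadings),
                 pc1_fraction = vf[1],
                 pc2_fraction = if (length(vf) > 1) vf[2] else NA_real_,
                 pc3_fraction = if (length(vf) > 2) vf[3] else NA_real_,
                 first3_fraction = sum(vf[seq_len(min(3, length(vf)))]))
}

#' Tidy a G-matrix structure test
#' @param x a [gmatrix_structure_test()] object.
#' @param ... unused.
#' @return one-row tibble: timepoint, n_genes, statistic, p_value.
#' @export
tidy.gmatrix_test <- function(x, ...) {
  tibble::tibble(timepoint = x$timepoint, n_genes = x$n_genes,
                 statistic = x$statistic, p_value = x$p_value)
}

#' Tidy an interactor-vs-random permutation test
#' @param x an [interactor_vs_random_test()] object.
#' @param ... unused.
#' @return one-row tibble with observed/null means, CI and p.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(timepoint = x$timepoint, n_edges = x$n_edges,
                 observed_mean_r2 = x$observed,
                 null_mean_r2 = mean(x$null_stats),
                 random_mean_r2 = x$random_mean,
                 random_ci_low = x$random_ci[1],
                 random_ci_high = x$random_ci[2],
                 p_value = x$p_value)
}
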