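# ggplot2 displays of the main result types.

#' Parental components across development
#'
#' Median scaled dam and sire components per time point on a log scale,
#' with inter-quartile whiskers — the standard display of how parental
#' contributions to expression variation change over development.
#'
#' @param object an [fit_ncii()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ncii_fit <- function(object, ...) {
  comp <- dplyr::filter(object$components,
                        .data$term %in% c("dam", "sire"))
  summ <- dplyr::summarise(
    dplyr::group_by(comp, .data$timepoint, .data$term),
    med = median(.data$scaled_mean),
    q1 = quantile(.data$scaled_mean, 0.25),
    q3 = quantile(.data$scaled_mean, 0.75), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$timepoint),
                                     y = .data$med, fill = .data$term)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time point", y = "scaled variance (median, IQR)",
                  fill = "parent") +
    ggplot2::theme_minimal()
}

#' Sensitive-edge fraction across development
#'
#' @param classifications tibble from [classify_edges()].
#' @return a ggplot of the proportion of sensitive (quantitative) edges
#'   per time point.
#' @export
plot_sensitive_fraction <- function(classifications) {
  cls <- classifications[!is.na(classifications$label), , drop = FALSE]
  frac <- dplyr::summarise(
    dplyr::group_by(cls, .data$timepoint),
    sensitive = mean(.data$label == "sensitive"),
    n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(frac, ggplot2::aes(x = .data$timepoint,
                                     y = .data$sensitive)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time point", y = "fraction of sensitive edges",
                  size = "edges") +
    ggplot2::theme_minimal()
}

#' Skeletal PCA overview
#'
#' Culture scores on the first two components, sized by nothing and
#' annotated with the variance fraction each explains.
#'
#' @param object a [skeletal_pca()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.skeletal_pca <- function(object, ...) {
  vf <- round(100 * object$variance_fraction[1:2], 1)
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("PC1 (", vf[1], "%)"),
                  y = paste0("PC2 (", vf[2], "%)")) +
    ggplot2::theme_minimal()
}

#' PLS contribution profile
#'
#' Weighted contribution scores of the expression measures, coloured by
#' time point, with the top fraction highlighted.
#'
#' @param object a [fit_2bpls()] object (with `contributions`, e.g. from
#'   [pls_expression_morphology()]; computed on the fly otherwise).
#' @param top_frac fraction highlighted (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pls2b <- function(object, top_frac = 0.05, ...) {
  contrib <- object$contributions %||% weighted_contributions(object)
  contrib$timepoint <- factor(measure_timepoint(contrib$measure))
  contrib$top <- contrib$measure %in% top_fraction(contrib, top_frac)
  ggplot2::ggplot(contrib, ggplot2::aes(x = .data$rank, y = .data$score,
                                        colour = .data$timepoint,
                                        shape = .data$top)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = "weighted contribution",
                  colour = "time point", shape = "top fraction") +
    ggplot2::theme_minimal()
}
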